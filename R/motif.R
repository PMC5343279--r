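#' Scan a sequence for E-boxes (CANNTG)
#'
#' Finds all forward-strand matches of the bHLH consensus `CANNTG`, where
#' `N` is any of A/C/G/T; an `N` in the *sequence* never matches.
#' Overlapping matches are reported by default. Scanning one strand is
#' exhaustive: the reverse complement of a CANNTG match is again CANNTG, so
#' double-strand scanning would double-count.
#'
#' @param seq A single sequence string over A/C/G/T/N (case-insensitive).
#' @param overlapping Count overlapping matches (default `TRUE`)?
#' @return A tibble with `position` (0-based match start) and `motif` (the
#'   matched 6-mer).
#' @examples
#' scan_eboxes("CACATGTG")  # two overlapping hits, positions 0 and 2
#' @export
scan_eboxes <- function(seq, overlapping = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  pattern <- if (overlapping) "(?=CA[ACGT]{2}TG)" else "CA[ACGT]{2}TG"
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(position = integer(), motif = character()))
  }
  pos <- as.integer(m)
  tibble::tibble(position = pos - 1L,
                 motif = substring(seq, pos, pos + 5L))
}

#' Background E-box density over a set of sequences
#'
#' Pools E-box counts and lengths over the input sequences (typically all
#' intronic sequence), giving motifs per bp and its reciprocal, bp per
#' motif. In mouse intronic sequence roughly one E-box occurs per ~180 bp.
#'
#' @param seqs Character vector of sequences.
#' @param overlapping Passed to [scan_eboxes()].
#' @return A one-row tibble: `n_hits`, `total_bp`, `density` (motifs/bp),
#'   `bp_per_motif`.
#' @export
ebox_density <- function(seqs, overlapping = TRUE) {
  if (length(seqs) == 0L || sum(nchar(seqs)) == 0L) {
    stop("need at least one non-empty sequence", call. = FALSE)
  }
  n_hits <- sum(purrr::map_int(seqs, ~ nrow(scan_eboxes(.x, overlapping))))
  total_bp <- sum(nchar(seqs))
  tibble::tibble(n_hits = n_hits, total_bp = total_bp,
                 density = n_hits / total_bp,
                 bp_per_motif = total_bp / n_hits)
}

#' Fold enrichment of a motif cluster over background density
#'
#' Compares the observed motif density inside a window with a genome-wide
#' background density: `(observed_count / window_len) / background_density`.
#' Four E-boxes in a ~130 bp window against the ~1/180 bp intronic
#' background is approximately fivefold enrichment.
#'
#' @param observed_count Number of motifs observed in the window.
#' @param window_len Window length in bp (> 0).
#' @param background_density Background motif density in motifs/bp (> 0).
#' @return Fold enrichment (1 = exactly the background expectation).
#' @examples
#' cluster_enrichment(4, 130, 1 / 180)  # ~5.5
#' @export
cluster_enrichment <- function(observed_count, window_len,
                               background_density) {
  if (window_len <= 0) stop("window_len must be > 0", call. = FALSE)
  if (background_density <= 0) {
    stop("background_density must be > 0", call. = FALSE)
  }
  (observed_count / window_len) / background_density
}

#' Per-base values of a signal track over a region
#'
#' Expands a segment track to one value per base over
#' `[start, end)`; uncovered positions take `uncovered` (0 by default;
#' `NA` to skip them in downstream window means).
#'
#' @param track Signal-track tibble.
#' @param chrom Chromosome name.
#' @param start,end Region in 0-based half-open coordinates.
#' @param uncovered Value for uncovered bases.
#' @return Numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start, end, uncovered = 0) {
  stopifnot(end > start)
  out <- rep(uncovered, end - start)
  seg <- track[track$chrom == chrom & track$end > start & track$start < end, ,
               drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    a <- max(seg$start[i], start) - start + 1
    b <- min(seg$end[i], end) - start
    out[a:b] <- seg$value[i]
  }
  out
}

#' Sliding-window mean profile across a span
#'
#' Computes the mean of per-base values in every window of `window` bp,
#' advanced by `step` bp across the span, the construction behind
#' sliding-window conservation (PhyloP) and binding-score (MACS score)
#' profiles. With `window = 50`, `span = 550`, `step = 1` this yields 501
#' windows. Window means ignore `NA` values when `na_rm = TRUE`.
#'
#' @param values Numeric vector of per-base values spanning the region
#'   (e.g. from [track_values()]).
#' @param window Window size in bp (default 50).
#' @param step Step between window starts in bp (default 1).
#' @param start Coordinate of the first base of `values`; window midpoints
#'   are reported relative to it (default 0).
#' @param na_rm Drop `NA` bases from window means (default `FALSE`).
#' @return A `window_profile` tibble with `midpoint` and `mean`, one row
#'   per window.
#' @export
sliding_profile <- function(values, window = 50, step = 1, start = 0,
                            na_rm = FALSE) {
  span <- length(values)
  if (span < window) {
    stop("span (", span, ") is smaller than window (", window, ")",
         call. = FALSE)
  }
  offsets <- seq(0L, span - window, by = step)
  if (na_rm) {
    means <- purrr::map_dbl(offsets, function(o) {
      mean(values[(o + 1):(o + window)], na.rm = TRUE)
    })
  } else {
    cs <- c(0, cumsum(values))
    means <- (cs[offsets + window + 1] - cs[offsets + 1]) / window
  }
  out <- tibble::tibble(midpoint = start + offsets + window / 2,
                        mean = means)
  structure(out, class = c("window_profile", class(tibble::tibble())),
            window = window, step = step, span = span, origin = start)
}

#' Rank correlation between two window profiles
#'
#' Spearman correlation of window means between two profiles computed on
#' the same window grid (e.g. conservation vs binding score across the
#' same element).
#'
#' @param a,b `window_profile` tibbles from [sliding_profile()].
#' @return Spearman rank-correlation coefficient.
#' @export
profile_concordance <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !isTRUE(all.equal(a$midpoint - a$midpoint[1],
                        b$midpoint - b$midpoint[1]))) {
    stop("profiles are not on the same window grid", call. = FALSE)
  }
  cor(a$mean, b$mean, method = "spearman")
}

#' Exons and introns of gene models as flat interval tables
#'
#' @param genes Gene-model tibble from [read_gene_models()].
#' @return A tibble with `gene_id`, `transcript_id`, `chrom`, `start`,
#'   `end`, one row per exon (or per intron).
#' @export
gene_exons <- function(genes) {
  purrr::map(seq_len(nrow(genes)), function(i) {
    dplyr::mutate(genes$exons[[i]],
                  gene_id = genes$gene_id[i],
                  transcript_id = genes$transcript_id[i],
                  chrom = genes$chrom[i], .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' @rdname gene_exons
#' @export
gene_introns <- function(genes) {
  purrr::map(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    if (nrow(ex) < 2L) return(NULL)
    tibble::tibble(gene_id = genes$gene_id[i],
                   transcript_id = genes$transcript_id[i],
                   chrom = genes$chrom[i],
                   start = ex$end[-nrow(ex)],
                   end = ex$start[-1])
  }) |>
    dplyr::bind_rows()
}

#' Profiles of randomly selected exonic or intronic regions
#'
#' Samples `n` regions of length `span` from the exons (or introns) of the
#' gene models, computes the sliding-window profile of each against a
#' signal track, and averages them — the background against which an
#' element's own profile is compared.
#'
#' @param genes Gene-model tibble.
#' @param track Signal-track tibble (e.g. conservation).
#' @param n Number of regions to sample without replacement (default 20).
#' @param kind `"exonic"` or `"intronic"`.
#' @param span Region length in bp (default 550).
#' @param window,step Passed to [sliding_profile()].
#' @param seed Optional integer seed for reproducible sampling.
#' @return A list with `profiles` (tibble of per-region window means,
#'   keyed by `region_id`) and `mean_profile` (a `window_profile` of the
#'   across-region average).
#' @export
random_region_profiles <- function(genes, track, n = 20,
                                   kind = c("exonic", "intronic"),
                                   span = 550, window = 50, step = 1,
                                   seed = NULL) {
  kind <- match.arg(kind)
  regions <- if (kind == "exonic") gene_exons(genes) else gene_introns(genes)
  regions <- regions[regions$end - regions$start >= span, , drop = FALSE]
  if (nrow(regions) < n) {
    stop("only ", nrow(regions), " ", kind, " region(s) of length >= ", span,
         " available; need ", n, call. = FALSE)
  }
  sample_profiles <- function() {
    picked <- regions[sample.int(nrow(regions), n), , drop = FALSE]
    purrr::map(seq_len(n), function(i) {
      lo <- picked$start[i]
      slack <- (picked$end[i] - picked$start[i]) - span
      off <- if (slack > 0) sample.int(slack + 1L, 1L) - 1L else 0L
      vals <- track_values(track, picked$chrom[i], lo + off, lo + off + span)
      prof <- sliding_profile(vals, window = window, step = step)
      dplyr::mutate(tibble::as_tibble(prof), region_id = i, .before = 1)
    })
  }
  profs <- if (is.null(seed)) {
    sample_profiles()
  } else {
    withr::with_seed(seed, sample_profiles())
  }
  flat <- dplyr::bind_rows(profs)
  mean_prof <- flat |>
    dplyr::group_by(.data$midpoint) |>
    dplyr::summarise(mean = mean(.data$mean), .groups = "drop")
  mean_prof <- structure(mean_prof,
                         class = c("window_profile", class(tibble::tibble())),
                         window = window, step = step, span = span, origin = 0)
  list(profiles = flat, mean_profile = mean_prof)
}
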