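#' Derive high-confidence consensus peaks from replicate peak sets
#'
#' A consensus peak is a genomic region supported by every replicate
#' ChIP-Seq experiment: the maximal region of pooled peak coverage that
#' contains at least `min_overlap` bp shared by all replicates. The
#' reported interval is the base-wise intersection of the replicate peaks
#' within that region (the most conservative choice; the region all
#' antibodies support), or the pooled union when `coords = "union"`. Where
#' one replicate contributes several adjacent peaks to the same pooled
#' region, a single consensus peak is emitted.
#'
#' Each replicate contributes the maximum score among its peaks overlapping
#' the consensus interval; the consensus score is the minimum of these
#' (conservative: the weakest supporting replicate).
#'
#' @param peak_sets A list of two or more peak tibbles (`chrom`, `start`,
#'   `end`, optional `name`, `score`), e.g. from [read_peaks()]. List names
#'   label the replicate score columns.
#' @param min_overlap Minimum number of base pairs that must be shared by
#'   all replicates (default 1).
#' @param coords `"intersection"` (default) or `"union"`: whether the
#'   reported interval is the base-wise intersection or the pooled span of
#'   the supporting region.
#' @return A `consensus_peaks` tibble, ordered by (chrom, start), with
#'   columns `chrom`, `start`, `end`, `midpoint`, one `score_<replicate>`
#'   column per input set, `min_score`, and a `core` list-column holding
#'   the exact base-wise intersection segments of each consensus region.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200, score = 60)
#' b <- tibble::tibble(chrom = "chr1", start = 150, end = 250, score = 55)
#' c <- tibble::tibble(chrom = "chr1", start = 180, end = 300, score = 80)
#' consensus_peaks(list(a, b, c))
#' @export
consensus_peaks <- function(peak_sets, min_overlap = 1,
                            coords = c("intersection", "union")) {
  coords <- match.arg(coords)
  if (!is.list(peak_sets) || length(peak_sets) < 2L) {
    stop("need at least 2 replicate peak sets", call. = FALSE)
  }
  stopifnot(min_overlap >= 1)
  n_rep <- length(peak_sets)
  rep_names <- names(peak_sets)
  if (is.null(rep_names) || any(!nzchar(rep_names))) {
    rep_names <- paste0("rep", seq_len(n_rep))
  }
  chroms <- Reduce(intersect, lapply(peak_sets, function(p) unique(p$chrom)))
  rows <- purrr::map(sort(chroms), function(ch) {
    consensus_one_chrom(peak_sets, ch, min_overlap, coords)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), midpoint = numeric(),
                          core = list())
    for (rn in rep_names) out[[paste0("score_", rn)]] <- numeric()
    out$min_score <- numeric()
  } else {
    names(out)[match(paste0("score_", seq_len(n_rep)), names(out))] <-
      paste0("score_", rep_names)
  }
  out <- dplyr::relocate(out, "core", .after = dplyr::last_col()) |>
    dplyr::arrange(.data$chrom, .data$start)
  new_consensus_peaks(out, rep_names)
}

new_consensus_peaks <- function(x, rep_names) {
  structure(x,
            class = c("consensus_peaks", class(tibble::tibble())),
            replicates = rep_names)
}

consensus_one_chrom <- function(peak_sets, ch, min_overlap, coords) {
  raw <- lapply(peak_sets, function(p) p[p$chrom == ch, , drop = FALSE])
  ir <- lapply(raw, function(q) {
    IRanges::reduce(IRanges::IRanges(start = q$start + 1, end = q$end))
  })
  core <- Reduce(IRanges::intersect, ir)
  pooled <- IRanges::reduce(do.call(c, unname(ir)))
  # keep only pooled regions whose shared core totals >= min_overlap bp
  hit <- IRanges::findOverlaps(core, pooled, select = "first")
  if (length(core) == 0L) return(NULL)
  groups <- split(seq_along(core), hit)
  rows <- purrr::map(groups, function(idx) {
    shared_bp <- sum(IRanges::width(core[idx]))
    if (shared_bp < min_overlap) return(NULL)
    if (coords == "intersection") {
      start1 <- min(IRanges::start(core[idx]))
      end1 <- max(IRanges::end(core[idx]))
    } else {
      region <- pooled[hit[idx[1]]]
      start1 <- IRanges::start(region)
      end1 <- IRanges::end(region)
    }
    hull <- IRanges::IRanges(start = start1, end = end1)
    scores <- purrr::map_dbl(raw, function(q) {
      if (!"score" %in% names(q) || nrow(q) == 0L) return(NA_real_)
      qr <- IRanges::IRanges(start = q$start + 1, end = q$end)
      ov <- IRanges::findOverlaps(hull, qr)
      s <- q$score[S4Vectors::subjectHits(ov)]
      if (length(s) == 0L || all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
    })
    start0 <- start1 - 1
    row <- tibble::tibble(
      chrom = ch, start = start0, end = end1,
      midpoint = floor((start0 + end1) / 2),
      core = list(tibble::tibble(start = IRanges::start(core[idx]) - 1,
                                 end = IRanges::end(core[idx])))
    )
    for (k in seq_along(scores)) row[[paste0("score_", k)]] <- scores[k]
    row$min_score <- if (all(is.na(scores))) NA_real_ else min(scores, na.rm = TRUE)
    row
  })
  dplyr::bind_rows(rows)
}

#' Convert between peak-calling scores and p-values
#'
#' Peak scores follow the MACS convention `score = -10 * log10(p)`: a
#' p-value of 1e-5 (the usual peak-calling cutoff) corresponds to a score
#' of 50. The two functions are mutually inverse and monotone.
#'
#' @param score Non-negative peak score(s).
#' @param p P-value(s) in (0, 1].
#' @return `score_to_pvalue()` returns p-values; `pvalue_to_score()`
#'   returns scores.
#' @examples
#' pvalue_to_score(1e-5)  # 50
#' score_to_pvalue(50)    # 1e-5
#' @export
score_to_pvalue <- function(score) {
  if (any(score < 0)) stop("score must be >= 0", call. = FALSE)
  10^(-score / 10)
}

#' @rdname score_to_pvalue
#' @export
pvalue_to_score <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]", call. = FALSE)
  -10 * log10(p)
}
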