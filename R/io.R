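#' Read peak calls from BED or narrowPeak files
#'
#' Peaks are returned as a tibble in 0-based half-open coordinates, one row
#' per interval. For BED files the score is taken from column 5; for
#' narrowPeak files it is taken from the signalValue column (7) by default,
#' or from the `-log10(p)` column (8) when `narrowpeak_score = "pvalue"`.
#' Peak-caller scores follow the `-10*log10(p)` convention (see
#' [score_to_pvalue()]).
#'
#' @param path Path to a tab-separated BED3/BED5 or narrowPeak file.
#' @param dialect `"bed"` or `"narrowPeak"`.
#' @param narrowpeak_score Which narrowPeak column provides the score:
#'   `"signal"` (column 7, default) or `"pvalue"` (column 8, on the
#'   `-log10` scale).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`.
#'   `score` is `NA` for BED3 input.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpk\t50", f)
#' read_peaks(f)
#' @export
read_peaks <- function(path, dialect = c("bed", "narrowPeak"),
                       narrowpeak_score = c("signal", "pvalue")) {
  dialect <- match.arg(dialect)
  narrowpeak_score <- match.arg(narrowpeak_score)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_peaks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- if (dialect == "narrowPeak") 8L else 3L
  score_col <- switch(dialect,
    bed = 5L,
    narrowPeak = if (narrowpeak_score == "signal") 7L else 8L
  )
  rows <- purrr::imap(fields, function(f, i) {
    if (length(f) < min_cols) {
      stop("line ", i, ": expected >= ", min_cols, " tab-separated columns, got ",
           length(f), call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      stop("line ", i, ": non-numeric coordinates", call. = FALSE)
    }
    score <- if (length(f) >= score_col) {
      suppressWarnings(as.numeric(f[score_col]))
    } else {
      NA_real_
    }
    tibble::tibble(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4L) f[4] else NA_character_,
      score = score
    )
  })
  peaks <- dplyr::bind_rows(rows)
  bad <- which(peaks$start < 0 | peaks$end <= peaks$start)
  if (length(bad) > 0L) {
    stop("line ", bad[1], ": invalid interval (need 0 <= start < end)",
         call. = FALSE)
  }
  bad_score <- which(!is.na(peaks$score) & peaks$score < 0)
  if (length(bad_score) > 0L) {
    stop("line ", bad_score[1], ": negative score", call. = FALSE)
  }
  peaks
}

empty_peaks <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 name = character(), score = numeric())
}

#' Write peaks to a BED5 file
#'
#' Inverse of [read_peaks()] for the `"bed"` dialect; missing names are
#' written as `.` and missing scores as `0`.
#'
#' @param peaks Tibble with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  name <- if ("name" %in% names(peaks)) peaks$name else rep(NA_character_, nrow(peaks))
  score <- if ("score" %in% names(peaks)) peaks$score else rep(NA_real_, nrow(peaks))
  name[is.na(name)] <- "."
  lines <- paste(peaks$chrom, fmt_coord(peaks$start), fmt_coord(peaks$end),
                 name, fmt_num(ifelse(is.na(score), 0, score)), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

fmt_coord <- function(x) sprintf("%.0f", x)
fmt_num <- function(x) sprintf("%.10g", x)

#' Read a signal track from a bedGraph file
#'
#' bedGraph is the text track format used for histone-mark, CTCF,
#' conservation and binding-score signal: four tab-separated columns
#' (`chrom`, `start`, `end`, `value`) in 0-based half-open coordinates.
#' Segments within a chromosome must not overlap; they are returned sorted.
#'
#' @param path Path to a bedGraph file.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_track <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), value = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_cols <- lengths(fields)
  if (any(n_cols < 4L)) {
    stop("line ", which(n_cols < 4L)[1], ": bedGraph needs 4 columns",
         call. = FALSE)
  }
  track <- tibble::tibble(
    chrom = purrr::map_chr(fields, 1),
    start = as.numeric(purrr::map_chr(fields, 2)),
    end = as.numeric(purrr::map_chr(fields, 3)),
    value = as.numeric(purrr::map_chr(fields, 4))
  )
  if (anyNA(track$start) || anyNA(track$end) || anyNA(track$value) ||
      any(!is.finite(track$value))) {
    stop("bedGraph contains non-numeric or non-finite fields", call. = FALSE)
  }
  if (any(track$end <= track$start) || any(track$start < 0)) {
    stop("bedGraph contains invalid intervals", call. = FALSE)
  }
  track <- dplyr::arrange(track, .data$chrom, .data$start)
  check_track_disjoint(track)
  track
}

check_track_disjoint <- function(track) {
  overlap <- track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      bad = dplyr::n() > 1L && any(.data$start[-1] < .data$end[-dplyr::n()]),
      .groups = "drop"
    )
  if (any(overlap$bad)) {
    stop("track has overlapping segments on ",
         paste(overlap$chrom[overlap$bad], collapse = ", "), call. = FALSE)
  }
  invisible(track)
}

#' Write a signal track to a bedGraph file
#'
#' Inverse of [read_track()]; `read_track(write_track(x))` reproduces `x`.
#'
#' @param track Tibble with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  track <- dplyr::arrange(track, .data$chrom, .data$start)
  lines <- paste(track$chrom, fmt_coord(track$start), fmt_coord(track$end),
                 fmt_num(track$value), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from BED12 or a minimal GTF
#'
#' Each transcript becomes one row carrying its strand-aware TSS and an
#' `exons` list-column of per-exon tibbles (`start`, `end`, 0-based
#' half-open, sorted). The TSS is the 5' end of the transcript: `start` on
#' the plus strand, `end - 1` on the minus strand. Introns are the gaps
#' between consecutive exons.
#'
#' For BED12 the record name is the transcript id; a `gene|transcript` name
#' is split into the two ids. The minimal GTF dialect reads `exon` features
#' and requires `gene_id` and `transcript_id` attributes.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed12"` or `"gtf_min"`.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, `exons`.
#' @export
read_gene_models <- function(path, dialect = c("bed12", "gtf_min")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  models <- switch(dialect,
    bed12 = read_bed12(path),
    gtf_min = read_gtf_min(path)
  )
  validate_gene_models(models)
}

read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- purrr::imap(strsplit(lines, "\t", fixed = TRUE), function(f, i) {
    if (length(f) < 12L) {
      stop("line ", i, ": BED12 needs 12 columns", call. = FALSE)
    }
    strand <- f[6]
    if (!strand %in% c("+", "-")) {
      stop("line ", i, ": missing or invalid strand '", strand, "'",
           call. = FALSE)
    }
    start <- as.numeric(f[2]); end <- as.numeric(f[3])
    n_blocks <- as.integer(f[10])
    sizes <- as.numeric(strsplit(f[11], ",", fixed = TRUE)[[1]])
    offsets <- as.numeric(strsplit(f[12], ",", fixed = TRUE)[[1]])
    if (length(sizes) != n_blocks || length(offsets) != n_blocks) {
      stop("line ", i, ": blockCount disagrees with block lists", call. = FALSE)
    }
    if (is.unsorted(offsets, strictly = TRUE) && n_blocks > 1L) {
      stop("line ", i, ": exon blocks out of order", call. = FALSE)
    }
    ids <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    gene_id <- ids[1]
    transcript_id <- if (length(ids) > 1L) ids[2] else ids[1]
    ex_start <- start + offsets
    ex_end <- ex_start + sizes
    tibble::tibble(
      gene_id = gene_id, transcript_id = transcript_id,
      chrom = f[1], strand = strand, start = start, end = end,
      exons = list(tibble::tibble(start = ex_start, end = ex_end))
    )
  })
  dplyr::bind_rows(rows)
}

read_gtf_min <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  exon_rows <- purrr::imap(fields, function(f, i) {
    if (length(f) < 9L) {
      stop("line ", i, ": GTF needs 9 columns", call. = FALSE)
    }
    if (f[3] != "exon") return(NULL)
    if (!f[7] %in% c("+", "-")) {
      stop("line ", i, ": missing or invalid strand '", f[7], "'",
           call. = FALSE)
    }
    gid <- gtf_attr(f[9], "gene_id")
    tid <- gtf_attr(f[9], "transcript_id")
    if (is.na(gid) || is.na(tid)) {
      stop("line ", i, ": gene_id/transcript_id attribute missing",
           call. = FALSE)
    }
    tibble::tibble(gene_id = gid, transcript_id = tid, chrom = f[1],
                   strand = f[7],
                   exon_start = as.numeric(f[4]) - 1,  # GTF is 1-based closed
                   exon_end = as.numeric(f[5]))
  })
  exons <- dplyr::bind_rows(exon_rows)
  if (nrow(exons) == 0L) {
    stop("no exon records found", call. = FALSE)
  }
  exons |>
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$chrom,
                    .data$strand) |>
    dplyr::arrange(.data$exon_start, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(
        start = min(d$exon_start), end = max(d$exon_end),
        exons = list(tibble::tibble(start = d$exon_start,
                                    end = d$exon_end))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "transcript_id", "chrom", "strand",
                  "start", "end", "exons")
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]+)"'), attrs))[[1]]
  if (length(m) < 2L) NA_character_ else m[2]
}

validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    if (nrow(ex) == 0L) {
      stop("transcript ", models$transcript_id[i], " has no exons",
           call. = FALSE)
    }
    if (is.unsorted(ex$start, strictly = TRUE) && nrow(ex) > 1L) {
      stop("transcript ", models$transcript_id[i], ": exons out of order",
           call. = FALSE)
    }
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("transcript ", models$transcript_id[i], ": overlapping exons",
           call. = FALSE)
    }
    if (min(ex$start) < models$start[i] || max(ex$end) > models$end[i]) {
      stop("transcript ", models$transcript_id[i],
           ": exons outside transcript span", call. = FALSE)
    }
  }
  models$tss <- ifelse(models$strand == "+", models$start, models$end - 1)
  dplyr::relocate(models, "tss", .after = "end") |>
    dplyr::relocate("exons", .after = dplyr::last_col())
}

#' Write gene models as BED12
#'
#' @param models Gene-model tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- purrr::map_chr(seq_len(nrow(models)), function(i) {
    ex <- models$exons[[i]]
    name <- if (models$gene_id[i] == models$transcript_id[i]) {
      models$transcript_id[i]
    } else {
      paste0(models$gene_id[i], "|", models$transcript_id[i])
    }
    paste(models$chrom[i], fmt_coord(models$start[i]), fmt_coord(models$end[i]),
          name, 0, models$strand[i],
          fmt_coord(models$start[i]), fmt_coord(models$end[i]), "0",
          nrow(ex),
          paste0(paste(fmt_coord(ex$end - ex$start), collapse = ","), ","),
          paste0(paste(fmt_coord(ex$start - models$start[i]), collapse = ","), ","),
          sep = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read and write genomic sequence as FASTA
#'
#' Thin wrappers around Biostrings returning plain named character vectors,
#' the sequence representation used throughout the package.
#'
#' @param path Path to a FASTA file.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L
  )
  invisible(path)
}

#' Read ChIP-qPCR / RT-qPCR Ct tables
#'
#' Expects a CSV with header `sample_id, antibody, amplicon, replicate, ct`.
#' `antibody` must be one of `target`, `control`, `input`; Ct values must be
#' positive and finite.
#'
#' @param path Path to the CSV file.
#' @return A tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          antibody = readr::col_character(),
                          amplicon = readr::col_character(),
                          replicate = readr::col_integer(),
                          ct = readr::col_double()
                        ))
  validate_ct_table(ct)
}

validate_ct_table <- function(ct) {
  required <- c("sample_id", "antibody", "amplicon", "replicate", "ct")
  missing <- setdiff(required, names(ct))
  if (length(missing) > 0L) {
    stop("Ct table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!ct$antibody %in% c("target", "control", "input"))) {
    stop("antibody must be one of target, control, input", call. = FALSE)
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("Ct values must be positive and finite", call. = FALSE)
  }
  tibble::as_tibble(ct)
}

#' Read per-cell fluorescence trace tables
#'
#' Expects a CSV with header `time_s, cell_id, condition, raw, background`,
#' one row per frame per cell; frames must lie on a uniform time grid.
#'
#' @param path Path to the CSV file.
#' @return A tibble of trace samples.
#' @export
read_traces <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          time_s = readr::col_double(),
                          cell_id = readr::col_character(),
                          condition = readr::col_character(),
                          raw = readr::col_double(),
                          background = readr::col_double()
                        ))
  if (any(!is.finite(tr$raw))) stop("non-finite intensities", call. = FALSE)
  tibble::as_tibble(tr)
}

#' Convert between internal and browser-style coordinates
#'
#' Internally all intervals are 0-based half-open (BED convention). Printed
#' genome-browser positions ("chr7: 102369602-102370206" style) are 1-based
#' and closed; these converters are the only place that convention is
#' touched.
#'
#' @param peaks Tibble with `start`, `end` columns.
#' @return The tibble with coordinates shifted to the other convention.
#' @export
to_browser_coords <- function(peaks) {
  dplyr::mutate(peaks, start = .data$start + 1)
}

#' @rdname to_browser_coords
#' @export
from_browser_coords <- function(peaks) {
  dplyr::mutate(peaks, start = .data$start - 1)
}
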