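#' Score peaks against a chromatin-mark signal track
#'
#' Each peak receives one score per track: by default the maximum value
#' among track segments overlapping the peak by at least 1 bp (a peak that
#' touches a called histone peak inherits that peak's score), or a
#' coverage-weighted mean over the peak with uncovered bases contributing 0
#' (`aggregate = "mean"`). Peaks overlapping no segment score 0.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param track Signal-track tibble (`chrom`, `start`, `end`, `value`),
#'   sorted and non-overlapping per chromosome (see [read_track()]).
#' @param aggregate `"max"` (default) or `"mean"`.
#' @return Numeric vector of scores, one per peak row.
#' @export
peak_mark_score <- function(peaks, track, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  check_track_disjoint(dplyr::arrange(track, .data$chrom, .data$start))
  out <- numeric(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    seg <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0L) next
    pr <- IRanges::IRanges(start = peaks$start[pi] + 1, end = peaks$end[pi])
    sr <- IRanges::IRanges(start = seg$start + 1, end = seg$end)
    ov <- IRanges::findOverlaps(pr, sr)
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    if (aggregate == "max") {
      agg <- tapply(seg$value[sh], qh, max)
      idx <- as.integer(names(agg))
    } else {
      w <- pmin(peaks$end[pi][qh], seg$end[sh]) -
        pmax(peaks$start[pi][qh], seg$start[sh])
      sums <- tapply(w * seg$value[sh], qh, sum)
      idx <- as.integer(names(sums))
      agg <- sums / (peaks$end[pi][idx] - peaks$start[pi][idx])
    }
    out[pi[idx]] <- as.numeric(agg)
  }
  out
}

#' Mean chromatin-mark scores per peak category, with a genome baseline
#'
#' Builds the category-by-mark matrix behind chromatin-context heat maps:
#' for every peak category (promoter, exonic, intronic, intergenic) and
#' every mark track, the mean per-peak mark score (see
#' [peak_mark_score()]), plus a `genome` baseline row per mark that is
#' independent of the peak set (see [genome_baseline()]).
#'
#' @param annotations A `peak_annotation` tibble from [annotate_peaks()].
#' @param tracks Named list of signal-track tibbles, one per mark. Names
#'   must be unique.
#' @param genome_size Total genome length in bp, for the baseline.
#' @param aggregate Per-peak aggregation rule passed to [peak_mark_score()].
#' @param baseline `"genome"` (default; expected score of a uniformly
#'   random base) or `"segments"` (mean over called segments only).
#' @return A `context_matrix` tibble in long form: `category`, `mark`,
#'   `mean_score`, `n`. Empty categories have `mean_score = NA` (flagged
#'   empty, not 0); the baseline row has `n = NA`.
#' @export
context_matrix <- function(annotations, tracks, genome_size,
                           aggregate = c("max", "mean"),
                           baseline = c("genome", "segments")) {
  aggregate <- match.arg(aggregate)
  baseline <- match.arg(baseline)
  if (is.null(names(tracks)) || anyDuplicated(names(tracks)) ||
      any(!nzchar(names(tracks)))) {
    stop("tracks must be a uniquely named list of mark tracks", call. = FALSE)
  }
  cells <- purrr::imap(tracks, function(track, mark) {
    score <- peak_mark_score(annotations, track, aggregate = aggregate)
    per_cat <- tibble::tibble(category = annotations$category, score = score) |>
      dplyr::group_by(.data$category, .drop = FALSE) |>
      dplyr::summarise(mean_score = mean(.data$score), n = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(mean_score = ifelse(.data$n == 0L, NA_real_,
                                        .data$mean_score),
                    category = as.character(.data$category))
    dplyr::bind_rows(
      per_cat,
      tibble::tibble(category = "genome",
                     mean_score = genome_baseline(track, genome_size,
                                                  method = baseline),
                     n = NA_integer_)
    ) |>
      dplyr::mutate(mark = mark)
  })
  out <- dplyr::bind_rows(cells) |>
    dplyr::mutate(category = factor(.data$category,
                                    c(peak_categories, "genome"))) |>
    dplyr::relocate("mark", .after = "category") |>
    dplyr::arrange(.data$mark, .data$category)
  structure(out, class = c("context_matrix", class(tibble::tibble())),
            genome_size = genome_size, aggregate = aggregate)
}

#' Genome-wide baseline score of a signal track
#'
#' The expected score of a uniformly random base:
#' `sum(value * segment_length) / genome_size`, with uncovered bases
#' contributing 0. With `method = "segments"` the mean is taken over
#' covered bases only.
#'
#' @param track Signal-track tibble.
#' @param genome_size Genome length in bp; must be at least the covered
#'   length.
#' @param method `"genome"` (default) or `"segments"`.
#' @return A single numeric baseline score (0 for an empty track).
#' @export
genome_baseline <- function(track, genome_size,
                            method = c("genome", "segments")) {
  method <- match.arg(method)
  if (nrow(track) == 0L) return(0)
  widths <- track$end - track$start
  covered <- sum(widths)
  if (covered > genome_size) {
    stop("track covers ", covered, " bp > genome_size ", genome_size,
         call. = FALSE)
  }
  total <- sum(track$value * widths)
  if (method == "genome") total / genome_size else total / covered
}
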