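#' Tidy a consensus peak set
#'
#' One row per peak per replicate, with the replicate score in long form.
#'
#' @param x A `consensus_peaks` object.
#' @param ... Unused.
#' @return A tibble: `chrom`, `start`, `end`, `midpoint`, `replicate`,
#'   `score`, `min_score`.
#' @export
tidy.consensus_peaks <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select(-"core") |>
    tidyr::pivot_longer(cols = dplyr::starts_with("score_"),
                        names_to = "replicate", values_to = "score",
                        names_prefix = "score_") |>
    dplyr::relocate("min_score", .after = "score")
}

#' @rdname tidy.consensus_peaks
#' @export
glance.consensus_peaks <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x),
    n_replicates = length(attr(x, "replicates")),
    median_width = stats::median(x$end - x$start),
    min_score = suppressWarnings(min(x$min_score, na.rm = TRUE)),
    max_score = suppressWarnings(max(x$min_score, na.rm = TRUE))
  )
}

#' Tidy a chromatin-context matrix
#'
#' @param x A `context_matrix` object (already long: category, mark,
#'   mean score, n).
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.context_matrix <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.context_matrix
#' @export
glance.context_matrix <- function(x, ...) {
  tibble::tibble(
    n_marks = dplyr::n_distinct(x$mark),
    n_categories = dplyr::n_distinct(x$category[x$category != "genome"]),
    genome_size = attr(x, "genome_size"),
    aggregate = attr(x, "aggregate")
  )
}

#' Tidy per-cell SOCE metrics
#'
#' @param x A `soce_metrics` object.
#' @param ... Unused.
#' @return A long tibble: `condition`, `cell_id`, `metric`, `value`.
#' @export
tidy.soce_metrics <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(cols = -c("condition", "cell_id"),
                        names_to = "metric", values_to = "value")
}

#' @rdname tidy.soce_metrics
#' @export
glance.soce_metrics <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_conditions = dplyr::n_distinct(x$condition)
  )
}

#' Tidy ChIP-qPCR enrichment results
#'
#' @param x A `chip_enrichment` object.
#' @param ... Unused.
#' @return A long tibble with one row per amplicon per quantity.
#' @export
tidy.chip_enrichment <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(cols = -"amplicon", names_to = "quantity",
                        values_to = "value")
}

#' @rdname tidy.chip_enrichment
#' @export
glance.chip_enrichment <- function(x, ...) {
  tibble::tibble(
    n_amplicons = nrow(x),
    max_fold = max(x$fold),
    min_fold = min(x$fold)
  )
}
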