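#' Adjust an input Ct for the input aliquot fraction
#'
#' ChIP input chromatin is typically a 10% aliquot; its Ct is adjusted to
#' represent the full input by subtracting `log2(1 / input_fraction)`
#' cycles — 3.32 (`log2(10)`) for a 10% aliquot. The full-precision
#' logarithm is used; 3.32 is its display rounding.
#'
#' @param input_ct Input Ct value(s).
#' @param input_fraction Fraction of the material used as input, in (0, 1]
#'   (default 0.10).
#' @return Adjusted input Ct value(s).
#' @examples
#' adjust_input_ct(25)          # 25 - log2(10) = 21.68
#' adjust_input_ct(25, 0.25)    # 25 - 2
#' @export
adjust_input_ct <- function(input_ct, input_fraction = 0.10) {
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    stop("input_fraction must be in (0, 1]", call. = FALSE)
  }
  input_ct - log2(1 / input_fraction)
}

#' Percent input from adjusted input and ChIP Ct values
#'
#' The input-normalized ChIP DNA amount:
#' `100 * 2^(adjusted_input_ct - chip_ct)`. A ChIP Ct equal to the
#' adjusted input Ct means 100% of input was recovered; each extra cycle
#' halves the percentage.
#'
#' @param adjusted_input_ct Adjusted input Ct (see [adjust_input_ct()]).
#' @param chip_ct ChIP Ct value(s).
#' @return Percent-input value(s).
#' @examples
#' percent_input(21.68, 21.68)  # 100
#' percent_input(21.68, 22.68)  # 50
#' @export
percent_input <- function(adjusted_input_ct, chip_ct) {
  if (any(!is.finite(adjusted_input_ct)) || any(!is.finite(chip_ct))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  100 * 2^(adjusted_input_ct - chip_ct)
}

#' ChIP-qPCR fold enrichment over a control antibody
#'
#' For each amplicon: percent input is computed for every target- and
#' control-antibody replicate against the (mean) adjusted input Ct, percent
#' inputs are averaged per antibody, and the target average is divided by
#' the control average. The control is typically an unrelated antibody
#' (e.g. anti-GFP) measured at the same amplicon.
#'
#' @param ct Ct tibble with columns `antibody` (`target`, `control`,
#'   `input`), `amplicon`, `replicate`, `ct` (see [read_ct_table()]).
#' @param input_fraction Input aliquot fraction (default 0.10).
#' @param aggregate How replicates are averaged: `"mean"` (arithmetic mean
#'   of percent inputs, default) or `"geomean"`.
#' @return A `chip_enrichment` tibble: `amplicon`, `percent_input_target`,
#'   `percent_input_control`, `fold`.
#' @export
fold_enrichment <- function(ct, input_fraction = 0.10,
                            aggregate = c("mean", "geomean")) {
  aggregate <- match.arg(aggregate)
  ct <- validate_ct_table(add_ct_defaults(ct))
  avg <- if (aggregate == "mean") {
    mean
  } else {
    function(x) exp(mean(log(x)))
  }
  out <- ct |>
    dplyr::group_by(.data$amplicon) |>
    dplyr::group_modify(function(d, key) {
      for (ab in c("input", "target", "control")) {
        if (!any(d$antibody == ab)) {
          stop("amplicon ", key$amplicon, ": no '", ab, "' records",
               call. = FALSE)
        }
      }
      adj <- adjust_input_ct(mean(d$ct[d$antibody == "input"]),
                             input_fraction)
      pi_t <- avg(percent_input(adj, d$ct[d$antibody == "target"]))
      pi_c <- avg(percent_input(adj, d$ct[d$antibody == "control"]))
      tibble::tibble(percent_input_target = pi_t,
                     percent_input_control = pi_c,
                     fold = pi_t / pi_c)
    }) |>
    dplyr::ungroup()
  structure(out, class = c("chip_enrichment", class(tibble::tibble())))
}

add_ct_defaults <- function(ct) {
  if (!"sample_id" %in% names(ct)) ct$sample_id <- "s1"
  if (!"replicate" %in% names(ct)) ct$replicate <- 1L
  ct
}

#' Relative expression by the delta-delta-Ct method
#'
#' RT-qPCR fold change of a target transcript relative to a reference
#' transcript (e.g. *Gapdh*) and a calibrator sample:
#' `2^-((ct_target - ct_reference) - (calibrator_target -
#' calibrator_reference))`.
#'
#' @param target_ct,reference_ct Sample Ct values for the target and
#'   reference transcripts.
#' @param calibrator_target_ct,calibrator_reference_ct Calibrator-sample
#'   Ct values for the same two transcripts.
#' @return Fold change(s); 1 means expression equal to the calibrator.
#' @export
relative_expression <- function(target_ct, reference_ct,
                                calibrator_target_ct,
                                calibrator_reference_ct) {
  cts <- c(target_ct, reference_ct, calibrator_target_ct,
           calibrator_reference_ct)
  if (any(!is.finite(cts))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  ddct <- (target_ct - reference_ct) -
    (calibrator_target_ct - calibrator_reference_ct)
  2^(-ddct)
}
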