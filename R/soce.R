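#' Normalize a fluorescence trace to delta-F over F0
#'
#' Background-subtracts a raw intensity series and divides by the minimum
#' of the background-subtracted signal (F0), so the normalized trace has a
#' minimum of exactly 1. The background is a scalar per imaging field (or
#' a per-frame series); it must not exceed the minimum raw signal.
#'
#' @param raw Raw intensity series (a.u.).
#' @param background Scalar or per-frame background (a.u., default 0).
#' @return Normalized series with `min(out) == 1`.
#' @examples
#' normalize_trace(c(12, 20, 12), background = 2)  # 1.0 1.8 1.0
#' @export
normalize_trace <- function(raw, background = 0) {
  if (any(!is.finite(raw))) stop("intensities must be finite", call. = FALSE)
  f <- raw - background
  f0 <- min(f)
  if (f0 <= 0) {
    stop("background exceeds signal: minimum after subtraction is <= 0",
         call. = FALSE)
  }
  f / f0
}

#' Segment a calcium-imaging record into protocol phases
#'
#' The store-depletion protocol has three phases: baseline in
#' calcium-free medium (`pre`, before thapsigargin), ER calcium release
#' (`wave1`, thapsigargin to calcium re-addition) and store-operated entry
#' (`wave2`, after calcium re-addition). Phases are half-open on the
#' right except the final one: `[0, tg)`, `[tg, ca)`, `[ca, end]`.
#'
#' @param times Time stamps in seconds, uniformly spaced, starting at 0.
#' @param tg_time Thapsigargin addition time (s).
#' @param ca_time Calcium re-addition time (s); must exceed `tg_time`.
#' @return Factor of phase labels (`pre`, `wave1`, `wave2`), one per time
#'   point.
#' @export
segment_phases <- function(times, tg_time, ca_time) {
  if (tg_time < 0 || ca_time > max(times) || tg_time >= ca_time) {
    stop("need 0 <= tg_time < ca_time <= end of record", call. = FALSE)
  }
  if (tg_time == 0) {
    warning("tg_time = 0: empty pre-stimulus window", call. = FALSE)
  }
  phase <- ifelse(times < tg_time, "pre",
                  ifelse(times < ca_time, "wave1", "wave2"))
  factor(phase, levels = c("pre", "wave1", "wave2"))
}

#' Peak heights and areas of the ER-release and SOCE waves
#'
#' Quantifies a normalized trace: the baseline is the mean of the
#' pre-stimulus phase (or the normalization floor of 1 when
#' `baseline = "floor"`); each wave's peak height is its maximum above
#' baseline (floored at 0); areas are trapezoidal integrals of the
#' baseline-subtracted trace clipped at 0. The SOCE area is split into an
#' early phase (first `early_s` seconds after calcium re-addition) and the
#' remaining late phase; early + late equals the total to numerical
#' precision.
#'
#' @param times Time stamps (s), uniform grid from 0.
#' @param values Normalized trace from [normalize_trace()].
#' @param tg_time,ca_time Protocol event times (s), see [segment_phases()].
#' @param early_s Length of the early SOCE phase in seconds (default 50).
#' @param baseline `"pre"` (mean of pre-stimulus window, default) or
#'   `"floor"` (the normalized minimum, 1).
#' @return A one-row tibble: `baseline_level`, `wave1_peak`, `wave2_peak`,
#'   `wave1_auc`, `wave2_auc_total`, `wave2_auc_early`, `wave2_auc_late`.
#'   Metrics of empty windows are `NA`.
#' @export
wave_metrics <- function(times, values, tg_time, ca_time, early_s = 50,
                         baseline = c("pre", "floor")) {
  baseline <- match.arg(baseline)
  phase <- segment_phases(times, tg_time, ca_time)
  base <- if (baseline == "floor" || !any(phase == "pre")) {
    1
  } else {
    mean(values[phase == "pre"])
  }
  end_t <- max(times)
  early_end <- min(ca_time + early_s, end_t)
  # augmented grid: event and phase-split times inserted by interpolation so
  # sub-areas add up exactly
  aug <- augment_grid(times, values, c(tg_time, ca_time, early_end))
  peak_in <- function(lo, hi, closed_hi) {
    sel <- times >= lo & (if (closed_hi) times <= hi else times < hi)
    if (!any(sel)) return(NA_real_)
    max(0, max(values[sel]) - base)
  }
  tibble::tibble(
    baseline_level = base,
    wave1_peak = peak_in(tg_time, ca_time, FALSE),
    wave2_peak = peak_in(ca_time, end_t, TRUE),
    wave1_auc = auc_clipped(aug, tg_time, ca_time, base),
    wave2_auc_total = auc_clipped(aug, ca_time, end_t, base),
    wave2_auc_early = auc_clipped(aug, ca_time, early_end, base),
    wave2_auc_late = auc_clipped(aug, early_end, end_t, base)
  )
}

augment_grid <- function(times, values, at) {
  at <- at[at > min(times) & at < max(times) & !(at %in% times)]
  if (length(at) > 0L) {
    v_at <- stats::approx(times, values, xout = at)$y
    ord <- order(c(times, at))
    times <- c(times, at)[ord]
    values <- c(values, v_at)[ord]
  }
  list(times = times, values = values)
}

auc_clipped <- function(aug, lo, hi, base) {
  sel <- aug$times >= lo & aug$times <= hi
  if (sum(sel) < 2L) return(NA_real_)
  t <- aug$times[sel]
  y <- pmax(aug$values[sel] - base, 0)
  sum((y[-1] + y[-length(y)]) / 2 * diff(t))
}

#' Quantify SOCE metrics for every cell in a trace table
#'
#' Applies [normalize_trace()] and [wave_metrics()] per cell to a long
#' trace table (one row per frame per cell).
#'
#' @param traces Tibble with columns `time_s`, `cell_id`, `condition`,
#'   `raw`, `background` (see [read_traces()]).
#' @param tg_time,ca_time,early_s,baseline Passed to [wave_metrics()].
#' @return A `soce_metrics` tibble, one row per cell, with `cell_id`,
#'   `condition` and the wave metrics.
#' @export
soce_metrics <- function(traces, tg_time, ca_time, early_s = 50,
                         baseline = c("pre", "floor")) {
  baseline <- match.arg(baseline)
  out <- traces |>
    dplyr::group_by(.data$condition, .data$cell_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      norm <- normalize_trace(d$raw, d$background)
      wave_metrics(d$time_s, norm, tg_time, ca_time, early_s = early_s,
                   baseline = baseline)
    }) |>
    dplyr::ungroup()
  structure(out, class = c("soce_metrics", class(tibble::tibble())))
}

#' Per-condition summary of SOCE metrics
#'
#' Median, quartiles and range of each wave metric per condition — the
#' numbers behind box plots of peak heights and areas — ready for external
#' statistical testing (e.g. `kruskal.test`). Conditions with no cells are
#' dropped with a warning.
#'
#' @param metrics A `soce_metrics` tibble from [soce_metrics()].
#' @return A `soce_summary` tibble: `condition`, `metric`, `n`, `median`,
#'   `q25`, `q75`, `min`, `max`.
#' @export
cohort_summary <- function(metrics) {
  long <- tibble::as_tibble(metrics) |>
    tidyr::pivot_longer(cols = -c("condition", "cell_id"),
                        names_to = "metric", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$condition, .data$metric) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      median = stats::median(.data$value, na.rm = TRUE),
      q25 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q75 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      .groups = "drop"
    )
  empty <- out$condition[out$n == 0L]
  if (length(empty) > 0L) {
    warning("dropping empty condition(s): ",
            paste(unique(empty), collapse = ", "), call. = FALSE)
    out <- out[out$n > 0L, , drop = FALSE]
  }
  structure(out, class = c("soce_summary", class(tibble::tibble())))
}

#' Pairwise ratios of condition medians
#'
#' For every metric and every ordered pair of conditions, the ratio of
#' their medians (e.g. knockdown / control SOCE peak height).
#'
#' @param summary A `soce_summary` tibble from [cohort_summary()].
#' @return A tibble: `metric`, `condition_1`, `condition_2`, `ratio`
#'   (median of condition 1 over condition 2).
#' @export
pairwise_ratios <- function(summary) {
  summary <- tibble::as_tibble(summary)
  conds <- unique(summary$condition)
  pairs <- expand.grid(condition_1 = conds, condition_2 = conds,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$condition_1 != pairs$condition_2, , drop = FALSE]
  tibble::as_tibble(pairs) |>
    dplyr::left_join(summary |> dplyr::select("condition", "metric",
                                              m1 = "median"),
                     by = c(condition_1 = "condition"),
                     relationship = "many-to-many") |>
    dplyr::left_join(summary |> dplyr::select("condition", "metric",
                                              m2 = "median"),
                     by = c(condition_2 = "condition", "metric")) |>
    dplyr::mutate(ratio = .data$m1 / .data$m2) |>
    dplyr::select("metric", "condition_1", "condition_2", "ratio") |>
    dplyr::arrange(.data$metric, .data$condition_1, .data$condition_2)
}
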