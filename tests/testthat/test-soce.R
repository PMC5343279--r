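test_that("delta-F/F0 normalization floors the trace at exactly 1", {
  expect_equal(normalize_trace(c(12, 20, 12), background = 2),
               c(1.0, 1.8, 1.0))
  expect_equal(normalize_trace(rep(10, 5), background = 2), rep(1, 5))
  expect_error(normalize_trace(c(5, 8), background = 5), "background")
  withr::local_seed(61)
  for (i in 1:25) {
    raw <- 100 + abs(rnorm(101, 20, 10))
    bg <- runif(1, 0, 50)
    expect_identical(min(normalize_trace(raw, bg)), 1)
  }
})

test_that("phase segmentation follows the depletion protocol timings", {
  times <- seq(0, 600, by = 6)
  ph <- segment_phases(times, 100, 400)
  expect_equal(range(times[ph == "pre"]), c(0, 96))
  expect_equal(range(times[ph == "wave1"]), c(102, 396))
  expect_equal(range(times[ph == "wave2"]), c(402, 600))
  expect_warning(segment_phases(times, 0, 400), "empty pre")
  expect_error(segment_phases(times, 100, 700), "<=")
  expect_error(segment_phases(times, 400, 100), "<")
})

test_that("a rectangular SOCE pulse yields closed-form peak and areas", {
  times <- seq(0, 462, by = 6)
  values <- ifelse(times >= 402, 2, 1)
  m <- wave_metrics(times, values, tg_time = 102, ca_time = 402,
                    early_s = 50)
  expect_equal(m$baseline_level, 1)
  expect_equal(m$wave1_peak, 0)
  expect_equal(m$wave2_peak, 1)
  expect_equal(m$wave2_auc_total, 60)
  expect_equal(m$wave2_auc_early, 50)
  expect_equal(m$wave2_auc_late, 10)

  flat <- wave_metrics(times, rep(1, length(times)), 102, 402)
  expect_equal(flat$wave1_peak, 0)
  expect_equal(flat$wave2_peak, 0)
  expect_equal(flat$wave1_auc, 0)
  expect_equal(flat$wave2_auc_total, 0)
})

test_that("early and late SOCE areas always sum to the total", {
  withr::local_seed(62)
  times <- seq(0, 600, by = 6)
  for (i in 1:20) {
    values <- 1 + abs(rnorm(length(times), 0.5, 0.5))
    early <- runif(1, 10, 150)
    m <- wave_metrics(times, values, 100, 400, early_s = early)
    expect_equal(m$wave2_auc_early + m$wave2_auc_late, m$wave2_auc_total,
                 tolerance = 1e-9)
    expect_gte(m$wave1_peak, 0)
    expect_gte(m$wave2_peak, 0)
  }
})

test_that("metrics are invariant to a constant offset with matched background", {
  withr::local_seed(63)
  times <- seq(0, 600, by = 6)
  raw <- 100 + 40 * exp(-(times - 420)^2 / 2000) + rnorm(length(times), 0, 1)
  m1 <- wave_metrics(times, normalize_trace(raw, 20), 100, 400)
  m2 <- wave_metrics(times, normalize_trace(raw + 55, 75), 100, 400)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("cohort summaries and ratios respect ordering invariances", {
  sim_tr <- sim_traces(sim_config(seed = 25,
                                  traces = list(n_cells = 6)))
  met <- soce_metrics(sim_tr, 100, 400)
  s1 <- cohort_summary(met)
  shuffled <- met[sample.int(nrow(met)), ]
  s2 <- cohort_summary(shuffled)
  expect_equal(dplyr::arrange(tibble::as_tibble(s1), condition, metric),
               dplyr::arrange(tibble::as_tibble(s2), condition, metric))

  one <- cohort_summary(met[1, ])
  expect_equal(one$median[one$metric == "wave2_peak"],
               met$wave2_peak[1])

  same <- dplyr::bind_rows(
    dplyr::mutate(met, condition = "a"),
    dplyr::mutate(met, condition = "b"))
  ratios <- pairwise_ratios(cohort_summary(same))
  expect_true(all(ratios$ratio == 1))
})

test_that("planted SOCE amplitude ratios are recovered from cohorts", {
  sim_tr <- sim_traces(sim_config(seed = 27))
  met <- soce_metrics(sim_tr, 100, 400)
  ratios <- pairwise_ratios(cohort_summary(met))
  r <- ratios$ratio[ratios$metric == "wave2_peak" &
                      ratios$condition_1 == "knockdown" &
                      ratios$condition_2 == "control"]
  expect_lt(abs(r / 1.4 - 1), 0.1)

  zero <- sim_traces(sim_config(seed = 27,
                                traces = list(noise_sd = 0, cell_cv = 0,
                                              soce_scale = c(off = 0),
                                              n_cells = 5)))
  mz <- soce_metrics(zero, 100, 400)
  expect_equal(mz$wave2_peak, rep(0, 5), tolerance = 1e-3)
})

test_that("tidiers reshape SOCE metrics", {
  sim_tr <- sim_traces(sim_config(seed = 25, traces = list(n_cells = 3)))
  met <- soce_metrics(sim_tr, 100, 400)
  td <- tidy(met)
  expect_equal(nrow(td), nrow(met) * 7)
  expect_equal(glance(met)$n_conditions, 2)
})
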