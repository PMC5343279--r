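test_that("the generator is deterministic given a config", {
  s1 <- simulate_dataset(sim_config(seed = 5))
  s2 <- simulate_dataset(sim_config(seed = 5))
  expect_identical(s1$annotation$sequence, s2$annotation$sequence)
  expect_identical(s1$truth_sites, s2$truth_sites)
  expect_identical(s1$replicates, s2$replicates)
  expect_identical(s1$tracks$conservation, s2$tracks$conservation)
  expect_identical(s1$ct_table, s2$ct_table)
  expect_identical(s1$traces, s2$traces)
  s3 <- simulate_dataset(sim_config(seed = 6))
  expect_false(identical(s1$annotation$sequence, s3$annotation$sequence))
})

test_that("gene layout respects the genome and errors when it cannot", {
  ann <- sim_annotation(sim_config(seed = 2))
  expect_equal(nrow(ann$genes), 24)
  ex <- gene_exons(ann$genes)
  expect_true(all(ex$start >= 0))
  # genes on one chromosome never overlap
  by_chrom <- split(ann$genes, ann$genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_error(sim_annotation(sim_config(genome = list(chrom_length = 2e4))),
               "do not fit")
})

test_that("replicate peaks reflect fn_rate, jitter and disjoint decoys", {
  cfg0 <- sim_config(seed = 3,
                     peaks = list(fn_rate = 0, jitter_sd = 0,
                                  fp_per_replicate = 0))
  sim0 <- simulate_dataset(cfg0)
  for (r in sim0$replicates) {
    expect_equal(r$start, sim0$truth_sites$start)
    expect_equal(r$end, sim0$truth_sites$end)
  }

  cfg_fn <- sim_config(seed = 9,
                       peaks = list(fn_rate = 0.5, n_true_sites = 96,
                                    fp_per_replicate = 0))
  ann <- sim_annotation(cfg_fn)
  truth <- sim_truth_sites(cfg_fn, ann)
  reps <- sim_replicate_peaks(cfg_fn, truth)
  for (r in reps) {
    # binomial(96, 0.5): within 4 SD of 48
    expect_lt(abs(nrow(r) - 48), 4 * sqrt(96 * 0.25))
  }

  # decoys never overlap truth sites, so decoys alone form no consensus
  sim <- simulate_dataset(sim_config(seed = 4))
  decoys <- lapply(sim$replicates, function(r) r[is.na(r$truth), ])
  tr <- sim$truth_sites
  for (d in decoys) {
    n_overlap <- sum(vapply(seq_len(nrow(d)), function(i) {
      any(tr$chrom == d$chrom[i] & tr$start < d$end[i] &
            tr$end > d$start[i])
    }, TRUE))
    expect_equal(n_overlap, 0)
  }
  expect_equal(nrow(consensus_peaks(decoys)), 0)
})

test_that("planted E-box clusters contain exactly the requested count", {
  withr::local_seed(10)
  seq <- rand_seq(1000)
  planted <- plant_ebox_cluster(seq, 400, n = 4, span = 130)
  window <- substring(planted, 401, 530)
  expect_equal(nrow(scan_eboxes(window)), 4)
  expect_equal(oracle_scan(window), scan_eboxes(window)$position)
  # bases outside the window untouched
  expect_equal(substring(planted, 1, 400), substring(seq, 1, 400))

  empty <- plant_ebox_cluster(seq, 400, n = 0, span = 130)
  expect_equal(nrow(scan_eboxes(substring(empty, 401, 530))), 0)
  expect_error(plant_ebox_cluster(seq, 400, n = 22, span = 130),
               "too small")
  expect_error(plant_ebox_cluster(seq, 950, n = 4, span = 130), "beyond")
})

test_that("mark tracks are enriched at their configured category", {
  sim <- simulate_dataset(sim_config(seed = 8))
  ann <- annotate_peaks(sim$truth_sites, sim$annotation$genes)
  for (mark in c("H3K4me3", "H3K36me3")) {
    cat <- unname(sim$config$marks[[mark]])
    score <- peak_mark_score(ann, sim$tracks$marks[[mark]])
    enriched <- mean(score[ann$category == cat])
    other <- mean(score[ann$category == "intergenic"])
    if (cat == "intergenic") other <- mean(score[ann$category == "promoter"])
    expect_gt(enriched, other)
  }
})

test_that("Ct tables invert the percent-input arithmetic at zero noise", {
  cfg <- sim_config(seed = 2, qpcr = list(ct_noise_sd = 0))
  ct <- sim_ct_table(cfg)
  enr <- fold_enrichment(ct, input_fraction = cfg$qpcr$input_fraction)
  planted <- attr(ct, "true_folds")
  expect_equal(sort(names(planted)), sort(enr$amplicon))
  expect_equal(enr$fold[match(names(planted), enr$amplicon)],
               unname(planted), tolerance = 1e-12)
  expect_error(sim_config(qpcr = list(true_folds = c(bad = -2))), "> 0")
})

test_that("simulated traces have the right grid and planted waves", {
  cfg <- sim_config(seed = 2)
  tr <- sim_traces(cfg)
  one <- tr[tr$cell_id == tr$cell_id[1], ]
  expect_equal(nrow(one), 101)  # 600 s / 6 s + 1
  expect_equal(one$time_s, seq(0, 600, by = 6))

  flat_cfg <- sim_config(seed = 2,
                         traces = list(noise_sd = 0, cell_cv = 0,
                                       soce_scale = c(a = 0), n_cells = 2))
  flat <- sim_traces(flat_cfg)
  met <- soce_metrics(flat, tg_time = 100, ca_time = 400)
  expect_equal(met$wave2_peak, rep(0, 2), tolerance = 1e-3)
  expect_error(sim_config(traces = list(tg_time_s = 500, ca_time_s = 400)))
})

test_that("written datasets parse back through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(seed = 12), dir = dir)
  expect_equal(read_fasta(sim$files[["genome"]]), sim$annotation$sequence)
  genes <- read_gene_models(sim$files[["genes"]])
  expect_equal(genes$tss, sim$annotation$genes$tss)
  expect_equal(read_track(sim$files[["conservation"]]),
               sim$tracks$conservation, tolerance = 1e-9)
  rep1 <- read_peaks(sim$files[["peaks_rep1"]])
  expect_equal(rep1$start, sim$replicates$rep1$start)
  expect_equal(read_ct_table(sim$files[["ct"]])$ct, sim$ct_table$ct,
               tolerance = 1e-9)
  expect_equal(nrow(read_traces(sim$files[["traces"]])), nrow(sim$traces))
})
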