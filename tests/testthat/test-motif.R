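test_that("E-box scanning matches brute-force 6-mer enumeration", {
  expect_equal(scan_eboxes("CAGCTG")$position, 0)
  expect_equal(scan_eboxes("CACATGTG")$position, c(0, 2))
  expect_equal(nrow(scan_eboxes("CANNTG")), 0)  # sequence N never matches
  expect_equal(nrow(scan_eboxes("cagctg")), 1)  # case-insensitive
  withr::local_seed(51)
  for (i in 1:25) {
    s <- rand_seq(sample(6:400, 1))
    expect_equal(scan_eboxes(s)$position, oracle_scan(s))
  }
  # non-overlapping mode is greedy left to right
  expect_equal(scan_eboxes("CACATGTG", overlapping = FALSE)$position, 0)
})

test_that("E-box counts are strand-symmetric", {
  withr::local_seed(52)
  for (i in 1:20) {
    s <- rand_seq(300)
    expect_equal(nrow(scan_eboxes(s)), nrow(scan_eboxes(revcomp(s))))
  }
})

test_that("background density pools hits over sequences", {
  # 10 copies of a 180 bp unit carrying exactly one E-box
  unit <- paste0(strrep("C", 100), "CACGTG", strrep("C", 74))
  expect_equal(oracle_scan(unit), 100)
  seqs <- rep(unit, 10)
  bg <- ebox_density(seqs)
  expect_equal(bg$n_hits, 10)
  expect_equal(bg$density, 1 / 180)
  expect_equal(bg$bp_per_motif, 180)
  # concatenation invariance
  expect_equal(ebox_density(paste(seqs, collapse = ""))$density,
               bg$density)
  expect_equal(ebox_density("TTTTTT")$density, 0)
  expect_error(ebox_density(character(0)), "non-empty")
})

test_that("cluster enrichment follows (obs/window)/background", {
  fold <- cluster_enrichment(4, 130, 1 / 180)
  expect_equal(fold, (4 / 130) * 180)
  expect_gt(fold, 5)  # 'approximately fivefold'
  expect_equal(cluster_enrichment(10, 1800, 1 / 180), 1)
  expect_equal(cluster_enrichment(4, 260, 1 / 180), fold / 2)
  expect_error(cluster_enrichment(4, 0, 1 / 180), "window_len")
  expect_error(cluster_enrichment(4, 130, 0), "background_density")
})

test_that("sliding-window profiles equal the naive moving average", {
  const <- sliding_profile(rep(3.5, 100), window = 10)
  expect_equal(const$mean, rep(3.5, 91))
  prof <- sliding_profile(rnorm(550), window = 50, step = 1)
  expect_equal(nrow(prof), 501)
  expect_equal(diff(prof$midpoint), rep(1, 500))
  withr::local_seed(53)
  for (i in 1:10) {
    v <- rnorm(sample(60:500, 1))
    w <- sample(5:50, 1)
    st <- sample(1:7, 1)
    p <- sliding_profile(v, window = w, step = st)
    expect_equal(p$mean, oracle_moving_avg(v, w, st), tolerance = 1e-9)
  }
  expect_error(sliding_profile(rnorm(10), window = 50), "smaller than")
})

test_that("track expansion feeds window means with 0 where uncovered", {
  tr <- tibble::tibble(chrom = "chr1", start = c(100, 300),
                       end = c(200, 350), value = c(10, 4))
  v <- track_values(tr, "chr1", 50, 400)
  expect_equal(length(v), 350)
  expect_equal(v[1:50], rep(0, 50))
  expect_equal(v[51:150], rep(10, 100))
  expect_equal(sum(v), 100 * 10 + 50 * 4)
  prof <- sliding_profile(v, window = 50, start = 50)
  expect_equal(prof$mean, oracle_moving_avg(v, 50), tolerance = 1e-9)
  # NA handling for gap-skipping means
  vna <- track_values(tr, "chr1", 50, 400, uncovered = NA)
  pna <- sliding_profile(vna, window = 50, start = 50, na_rm = TRUE)
  expect_true(is.nan(pna$mean[1]))  # window entirely in the leading gap
  expect_equal(pna$mean[2], 10)     # one covered base, NA-stripped mean
})

test_that("profile concordance is a Spearman correlation on one grid", {
  p <- sliding_profile(rnorm(200), window = 20)
  expect_equal(profile_concordance(p, p), 1)
  neg <- p
  neg$mean <- -neg$mean
  expect_equal(profile_concordance(p, neg), -1)
  other <- sliding_profile(rnorm(100), window = 20)
  expect_error(profile_concordance(p, other), "grid")
})

test_that("binding and conservation co-elevate at the planted element", {
  sim <- simulate_dataset(sim_config(seed = 23))
  el <- sim$ground_truth$element
  mid <- floor((el$start + el$end) / 2)
  lo <- mid - 275
  pc <- sliding_profile(track_values(sim$tracks$conservation, el$chrom,
                                     lo, lo + 550), window = 50)
  pb <- sliding_profile(track_values(sim$tracks$binding, el$chrom,
                                     lo, lo + 550), window = 50)
  expect_gt(profile_concordance(pc, pb), 0.8)
})

test_that("random region profiles are seeded and rank exons above introns", {
  sim <- simulate_dataset(sim_config(seed = 23))
  genes <- sim$annotation$genes
  cons_track <- sim$tracks$conservation
  ex1 <- random_region_profiles(genes, cons_track, n = 20, kind = "exonic",
                                seed = 99)
  ex2 <- random_region_profiles(genes, cons_track, n = 20, kind = "exonic",
                                seed = 99)
  expect_identical(ex1$profiles, ex2$profiles)
  intr <- random_region_profiles(genes, cons_track, n = 20,
                                 kind = "intronic", seed = 99)
  expect_gt(mean(ex1$mean_profile$mean), mean(intr$mean_profile$mean))
  single <- random_region_profiles(genes, cons_track, n = 1,
                                   kind = "exonic", seed = 1)
  expect_equal(single$mean_profile$mean, single$profiles$mean)
  expect_error(random_region_profiles(genes, cons_track, n = 10,
                                      kind = "exonic", span = 5000),
               "available")
})
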