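track1 <- function(start, end, value) {
  tibble::tibble(chrom = "chr1", start = start, end = end, value = value)
}

test_that("peak mark scores take the maximum overlapping segment", {
  tr <- track1(c(100, 300), c(200, 400), c(3, 7))
  pk <- tibble::tibble(chrom = "chr1", start = 150, end = 350)
  expect_equal(peak_mark_score(pk, tr), 7)
  expect_equal(peak_mark_score(tibble::tibble(chrom = "chr1", start = 500,
                                              end = 600), tr), 0)
  inside <- tibble::tibble(chrom = "chr1", start = 120, end = 140)
  expect_equal(peak_mark_score(inside, tr), 3)
  # coverage-weighted mean: 50 bp at 3 and 50 bp at 7 over a 200 bp peak
  expect_equal(peak_mark_score(pk, tr, aggregate = "mean"),
               (50 * 3 + 50 * 7) / 200)
})

test_that("enlarging a peak never decreases its max mark score", {
  withr::local_seed(31)
  for (i in 1:30) {
    starts <- sort(sample.int(900, 10)) * 100
    tr <- track1(starts, starts + 80, runif(10, 0, 10))
    s <- sample.int(9e4, 1)
    pk <- tibble::tibble(chrom = "chr1", start = s, end = s + 500)
    big <- tibble::tibble(chrom = "chr1", start = s - 200, end = s + 900)
    expect_gte(peak_mark_score(big, tr), peak_mark_score(pk, tr))
  }
})

test_that("genome baseline is the expected score of a random base", {
  expect_equal(genome_baseline(track1(0, 100, 10), 1000), 1.0)
  expect_equal(genome_baseline(track1(numeric(0), numeric(0), numeric(0)),
                               1000), 0)
  expect_equal(genome_baseline(track1(0, 1000, 4.2), 1000), 4.2)
  expect_equal(genome_baseline(track1(0, 100, 10), 1000,
                               method = "segments"), 10)
  expect_error(genome_baseline(track1(0, 2000, 1), 1000), "genome_size")
})

test_that("the context matrix has per-category means and a baseline row", {
  ann <- structure(
    tibble::tibble(chrom = "chr1",
                   start = c(100, 300, 500, 700),
                   end = c(200, 400, 600, 800),
                   category = factor(peak_categories, peak_categories)),
    class = c("peak_annotation", class(tibble::tibble())))
  flat <- track1(0, 1000, 5)
  cm <- context_matrix(ann, list(m1 = flat), genome_size = 1000)
  expect_equal(cm$mean_score[cm$category != "genome"], rep(5, 4))
  expect_equal(cm$mean_score[cm$category == "genome"], 5)

  # empty category is NA, not 0
  ann3 <- ann[1:3, ]
  cm3 <- context_matrix(ann3, list(m1 = track1(0, 100, 2)),
                        genome_size = 1000)
  expect_true(is.na(cm3$mean_score[cm3$category == "intergenic"]))
  expect_equal(cm3$n[cm3$category == "intergenic"], 0)

  expect_error(context_matrix(ann, list(track1(0, 10, 1)), 1000),
               "named")
  expect_error(context_matrix(ann, stats::setNames(list(flat, flat),
                                                   c("m", "m")), 1000),
               "named")
})

test_that("synthetic promoter-enriched marks rank categories correctly", {
  sim <- simulate_dataset(sim_config(seed = 19))
  ann <- annotate_peaks(consensus_peaks(sim$replicates),
                        sim$annotation$genes)
  genome_size <- sim$config$genome$n_chroms * sim$config$genome$chrom_length
  cm <- context_matrix(ann, sim$tracks$marks, genome_size = genome_size)
  get <- function(cat, mark) {
    cm$mean_score[cm$category == cat & cm$mark == mark]
  }
  expect_gt(get("promoter", "H3K4me3"), get("intergenic", "H3K4me3"))
  expect_gt(get("exonic", "H3K36me3"), get("promoter", "H3K36me3"))
  expect_gt(get("intergenic", "H3K9me3"), get("promoter", "H3K9me3"))
})

test_that("uniformly placed marks converge to the genome baseline", {
  withr::local_seed(33)
  genome_len <- 1e5
  starts <- (sample.int(genome_len / 100 - 1, 250) - 1) * 100
  tr <- track1(starts, starts + 90, rnorm(250, 5, 1))
  # width-1 probe peaks: each samples the track like a random base
  mids <- sample.int(genome_len - 1, 4000)
  pk <- tibble::tibble(chrom = "chr1", start = mids, end = mids + 1)
  observed <- mean(peak_mark_score(pk, tr))
  expected <- genome_baseline(tr, genome_len)
  expect_lt(abs(observed - expected), 0.2)
})
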