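# one plus-strand gene [1000, 5000) with a long first exon, and one
# minus-strand gene on chr2
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"), transcript_id = c("tA", "tB"),
    chrom = c("chr1", "chr2"), strand = c("+", "-"),
    start = c(1000, 10000), end = c(5000, 14000),
    tss = c(1000, 13999),
    exons = list(tibble::tibble(start = c(1000, 4000),
                                end = c(3500, 5000)),
                 tibble::tibble(start = c(10000, 13000),
                                end = c(11000, 14000)))
  )
}

peak_at <- function(mid, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = mid - 50, end = mid + 50)
}

test_that("midpoint classification follows the promoter-first priority", {
  g <- toy_genes()
  expect_equal(as.character(annotate_peaks(peak_at(1000), g)$category),
               "promoter")  # exactly at the TSS, inside exon 1
  # 1500 bp into exon 1: outside the +/-1000 window, inside the exon
  expect_equal(as.character(annotate_peaks(peak_at(2500), g)$category),
               "exonic")
  expect_equal(as.character(annotate_peaks(peak_at(3700), g)$category),
               "intronic")
  expect_equal(as.character(annotate_peaks(peak_at(8000), g)$category),
               "intergenic")
  # the window edge is closed: |d| == halfwidth is still promoter
  expect_equal(as.character(annotate_peaks(peak_at(2000), g)$category),
               "promoter")
  expect_equal(as.character(annotate_peaks(peak_at(2001), g)$category),
               "exonic")
  expect_warning(
    ann <- annotate_peaks(peak_at(500, "chrX"), g),
    "no gene models")
  expect_equal(as.character(ann$category), "intergenic")
  expect_true(is.na(ann$tss_distance))
  expect_error(annotate_peaks(peak_at(500, "chrX"), g,
                              unknown_chrom = "error"))
})

test_that("nearest TSS distance is signed by gene strand", {
  g <- toy_genes()
  expect_equal(nearest_tss(1000, g, "chr1")$tss_distance, 0)
  # two plus-strand TSSs at 1000 and 5000: midpoint 1600 is +600 from the
  # nearer one
  g2 <- dplyr::bind_rows(g[1, ], dplyr::mutate(g[1, ], gene_id = "gC",
                                               tss = 5000))
  expect_equal(nearest_tss(1600, g2, "chr1")$tss_distance, 600)
  # 500 bp upstream of a minus-strand TSS: upstream means larger coordinate
  expect_equal(nearest_tss(14499, g, "chr2")$tss_distance, -500)
  expect_equal(nearest_tss(13499, g, "chr2")$tss_distance, 500)
  # strand-flip oracle: mirrored layouts give mirrored signs
  withr::local_seed(21)
  for (i in 1:20) {
    tss <- sample.int(5000, 1) + 2000
    mid <- tss + sample(-1500:1500, 1)
    gp <- tibble::tibble(gene_id = "g", transcript_id = "t", chrom = "c",
                         strand = "+", start = tss, end = tss + 100,
                         tss = tss, exons = list(tibble::tibble(
                           start = tss, end = tss + 100)))
    gm <- dplyr::mutate(gp, strand = "-")
    expect_equal(nearest_tss(mid, gp, "c")$tss_distance,
                 -nearest_tss(mid, gm, "c")$tss_distance)
  }
  # ties break toward the lexicographically smaller gene_id
  gt <- dplyr::bind_rows(
    dplyr::mutate(g[1, ], gene_id = "zz", tss = 3000),
    dplyr::mutate(g[1, ], gene_id = "aa", tss = 5000))
  expect_equal(nearest_tss(4000, gt, "chr1")$nearest_gene, "aa")
  expect_error(nearest_tss(100, g, "chrX"), "no TSS")
})

test_that("categories partition the peak set and summaries add up", {
  sim <- simulate_dataset(sim_config(seed = 13))
  cons <- consensus_peaks(sim$replicates)
  ann <- annotate_peaks(cons, sim$annotation$genes)
  cs <- category_summary(ann)
  expect_equal(sum(cs$n), nrow(ann))
  expect_equal(sum(cs$percent), 100)
  h <- tss_distance_histogram(ann, binwidth = 500)
  expect_equal(sum(h$count), sum(!is.na(ann$tss_distance)))

  four <- structure(
    tibble::tibble(category = factor(peak_categories, peak_categories)),
    class = c("peak_annotation", class(tibble::tibble())))
  expect_equal(category_summary(four)$percent, rep(25, 4))
})

test_that("published-style category counts round to the printed percents", {
  counts <- c(promoter = 516, exonic = 0, intronic = 805, intergenic = 743)
  ann <- structure(
    tibble::tibble(category = factor(rep(names(counts), counts),
                                     peak_categories)),
    class = c("peak_annotation", class(tibble::tibble())))
  cs <- category_summary(ann)
  expect_equal(sum(cs$n), 2064)
  expect_equal(round(cs$percent[cs$category == "promoter"]), 25)
  expect_equal(round(cs$percent[cs$category == "intronic"]), 39)
  expect_equal(round(cs$percent[cs$category == "intergenic"]), 36)
})

test_that("planted site categories are recovered exactly", {
  sim <- simulate_dataset(sim_config(seed = 17))
  ann <- annotate_peaks(sim$truth_sites, sim$annotation$genes)
  expect_equal(as.character(ann$category), sim$truth_sites$category)
})
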