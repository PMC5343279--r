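# Independent brute-force oracles used to cross-check the implementation.

# Per-base boolean-AND consensus oracle: maximal runs of bases covered by
# every peak set, as a tibble of 0-based half-open runs.
oracle_and_runs <- function(peak_sets, genome_len) {
  cov <- rep(TRUE, genome_len)
  for (p in peak_sets) {
    v <- rep(FALSE, genome_len)
    for (i in seq_len(nrow(p))) {
      v[(p$start[i] + 1):p$end[i]] <- TRUE
    }
    cov <- cov & v
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

# All base-wise intersection segments of a consensus result, flattened.
flatten_core <- function(cons) {
  if (nrow(cons) == 0L) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  dplyr::bind_rows(cons$core) |> dplyr::arrange(start)
}

rand_peak_set <- function(n, genome_len, max_len = 500) {
  start <- sample.int(genome_len - max_len, n) - 1
  len <- sample.int(max_len, n)
  tibble::tibble(chrom = "chr1", start = start, end = start + len,
                 name = paste0("p", seq_len(n)),
                 score = round(runif(n, 10, 500), 2))
}

# Brute-force E-box scan: test every 6-mer explicitly.
oracle_scan <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  hits <- integer(0)
  if (n >= 6) {
    for (i in seq_len(n - 5)) {
      k <- substring(seq, i, i + 5)
      if (substring(k, 1, 2) == "CA" && substring(k, 5, 6) == "TG" &&
          !grepl("[^ACGT]", k)) {
        hits <- c(hits, i - 1L)
      }
    }
  }
  hits
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Naive O(n * w) moving average.
oracle_moving_avg <- function(values, window, step = 1) {
  offsets <- seq(0L, length(values) - window, by = step)
  vapply(offsets, function(o) mean(values[(o + 1):(o + window)]), 0)
}
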