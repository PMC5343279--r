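#' Classify peak midpoints against gene models
#'
#' Each peak is represented by its midpoint, `floor((start + end) / 2)`,
#' and classified as `promoter`, `exonic`, `intronic` or `intergenic`, in
#' that priority order:
#'
#' * promoter: within `promoter_halfwidth` bp (inclusive) of any
#'   transcript's strand-aware TSS, regardless of gene-body status;
#' * exonic: inside any annotated exon of any transcript;
#' * intronic: inside a transcript span but not in any exon;
#' * intergenic: none of the above.
#'
#' The signed distance to the closest TSS is also reported, positive
#' downstream and negative upstream relative to the gene's strand; ties in
#' absolute distance are broken toward the lexicographically smaller
#' `gene_id`.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, ...), e.g. from
#'   [consensus_peaks()]. An existing `midpoint` column is used as is.
#' @param genes Gene-model tibble from [read_gene_models()] or
#'   [sim_annotation()].
#' @param promoter_halfwidth Half-width of the promoter window around each
#'   TSS, in bp (default 1000; the window is closed, `|d| <=` half-width).
#' @param unknown_chrom What to do with peaks on chromosomes that carry no
#'   gene model: `"intergenic"` (default; classified intergenic with a
#'   warning, TSS distance `NA`) or `"error"`.
#' @return A `peak_annotation` tibble: the input columns plus `midpoint`,
#'   `category`, `nearest_gene` and `tss_distance`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_halfwidth = 1000,
                           unknown_chrom = c("intergenic", "error")) {
  unknown_chrom <- match.arg(unknown_chrom)
  stopifnot(promoter_halfwidth >= 0)
  # annotation columns are (re)derived here; drop stale ones from the input
  peaks <- dplyr::select(
    peaks, -dplyr::any_of(c("category", "nearest_gene", "tss_distance")))
  if (!"midpoint" %in% names(peaks)) {
    peaks <- dplyr::mutate(peaks, midpoint = floor((.data$start + .data$end) / 2))
  }
  no_genes <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(no_genes) > 0L) {
    msg <- paste("no gene models on chromosome(s):",
                 paste(no_genes, collapse = ", "))
    if (unknown_chrom == "error") stop(msg, call. = FALSE)
    warning(msg, "; classifying those peaks as intergenic", call. = FALSE)
  }
  ann <- purrr::map(seq_len(nrow(peaks)), function(i) {
    classify_one(peaks$chrom[i], peaks$midpoint[i], genes, promoter_halfwidth)
  })
  out <- dplyr::bind_cols(peaks, dplyr::bind_rows(ann))
  structure(out, class = c("peak_annotation", class(tibble::tibble())))
}

peak_categories <- c("promoter", "exonic", "intronic", "intergenic")

classify_one <- function(chrom, midpoint, genes, hw) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(tibble::tibble(category = factor("intergenic", peak_categories),
                          nearest_gene = NA_character_,
                          tss_distance = NA_real_))
  }
  dist <- ifelse(g$strand == "+", midpoint - g$tss, g$tss - midpoint)
  ord <- order(abs(dist), g$gene_id)
  nearest <- ord[1]
  in_exon <- any(purrr::map2_lgl(g$exons, seq_len(nrow(g)), function(ex, k) {
    any(ex$start <= midpoint & midpoint < ex$end)
  }))
  in_body <- any(g$start <= midpoint & midpoint < g$end)
  category <- if (abs(dist[nearest]) <= hw) {
    "promoter"
  } else if (in_exon) {
    "exonic"
  } else if (in_body) {
    "intronic"
  } else {
    "intergenic"
  }
  tibble::tibble(category = factor(category, peak_categories),
                 nearest_gene = g$gene_id[nearest],
                 tss_distance = dist[nearest])
}

#' Signed distance from a position to the closest TSS
#'
#' @param midpoint Position in bp (0-based).
#' @param genes Gene-model tibble restricted by the caller as needed; must
#'   contain at least one row on `chrom`.
#' @param chrom Chromosome of the position.
#' @return A one-row tibble with `nearest_gene` and `tss_distance` (signed:
#'   positive downstream of the TSS relative to gene strand).
#' @export
nearest_tss <- function(midpoint, genes, chrom) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) {
    stop("no TSS on chromosome ", chrom, call. = FALSE)
  }
  dist <- ifelse(g$strand == "+", midpoint - g$tss, g$tss - midpoint)
  ord <- order(abs(dist), g$gene_id)
  tibble::tibble(nearest_gene = g$gene_id[ord[1]],
                 tss_distance = dist[ord[1]])
}

#' Summarise peak categories
#'
#' Counts and percentages per category. The four categories partition the
#' peak set, so counts always sum to the number of peaks and percentages to
#' 100 (within rounding).
#'
#' @param annotations A `peak_annotation` tibble from [annotate_peaks()].
#' @return A tibble with `category`, `n`, `percent` (all four categories,
#'   including empty ones).
#' @export
category_summary <- function(annotations) {
  if (nrow(annotations) == 0L) {
    return(tibble::tibble(category = factor(character(), peak_categories),
                          n = integer(), percent = numeric()))
  }
  tibble::tibble(category = factor(peak_categories, peak_categories)) |>
    dplyr::left_join(
      dplyr::count(tibble::as_tibble(annotations), .data$category),
      by = "category"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  percent = 100 * .data$n / sum(.data$n))
}

#' Histogram of peak-midpoint distances to the closest TSS
#'
#' Bins the signed TSS distances from [annotate_peaks()]; bin `[b, b +
#' binwidth)` is labelled by its left edge. Peaks with undefined distance
#' (chromosomes without genes) are dropped with a message.
#'
#' @param annotations A `peak_annotation` tibble.
#' @param binwidth Bin width in bp (default 500).
#' @return A tibble with `bin_start`, `bin_mid`, `count`.
#' @export
tss_distance_histogram <- function(annotations, binwidth = 500) {
  d <- annotations$tss_distance
  if (anyNA(d)) {
    message("dropping ", sum(is.na(d)), " peak(s) with undefined TSS distance")
    d <- d[!is.na(d)]
  }
  if (length(d) == 0L) {
    return(tibble::tibble(bin_start = numeric(), bin_mid = numeric(),
                          count = integer()))
  }
  bin <- floor(d / binwidth) * binwidth
  tibble::tibble(bin_start = bin) |>
    dplyr::count(.data$bin_start, name = "count") |>
    dplyr::mutate(bin_mid = .data$bin_start + binwidth / 2) |>
    dplyr::relocate("bin_mid", .after = "bin_start")
}
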