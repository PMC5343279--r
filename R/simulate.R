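#' Configuration for the synthetic-data generator
#'
#' Builds the full parameter set for [simulate_dataset()] and friends. Each
#' argument is a list merged over the documented defaults, so only the
#' fields being changed need to be supplied. A single integer `seed` drives
#' every artifact; per-artifact sub-streams are derived from it
#' deterministically, so the same config is byte-reproducible.
#'
#' Defaults emulate the assayed system at desk scale: a two-chromosome
#' 100 kb-per-chromosome genome; 24 three-exon genes; 60 planted
#' transcription-factor binding sites (15 per genomic category) observed by
#' three replicate ChIP experiments with boundary jitter and decoy peaks;
#' chromatin-mark tracks enriched at their characteristic category;
#' a conserved intronic element carrying a 4-E-box/130 bp cluster against
#' a ~1/180 bp background density; ChIP-qPCR Ct tables with known fold
#' enrichments (including the landmark 35- and 100-fold targets); and
#' two-wave calcium traces sampled every 6 s for 600 s, with thapsigargin
#' at 100 s and calcium re-addition at 400 s.
#'
#' @param seed Integer master seed.
#' @param genome `n_chroms`, `chrom_length` (bp).
#' @param genes `n_genes`, `exons_per_gene` (>= 3), `exon_len`,
#'   `intron_len` (bp).
#' @param peaks `n_true_sites`, `site_len`, `jitter_sd` (bp),
#'   `fp_per_replicate`, `fn_rate` in `[0, 1)`, `n_replicates`,
#'   `true_score_mean`, `true_score_sd`, `decoy_score_mean`,
#'   `decoy_score_sd` (MACS-style scores).
#' @param marks Named character vector mapping mark name to its enriched
#'   category.
#' @param mark_signal `enriched_mean`, `background_mean`, `sd`,
#'   `n_background_segments`, `background_seg_len`.
#' @param motif `cluster_n`, `cluster_span` (bp), `background_density`
#'   (motifs/bp).
#' @param conservation `baseline_mean`, `exon_mean`, `element_mean`, `sd`,
#'   `tile` (bp), `bump_width` (bp), `binding_amp`.
#' @param qpcr `true_folds` (named vector, > 0), `ct_noise_sd`,
#'   `n_replicates`, `base_input_ct`, `control_percent_input`,
#'   `input_fraction`.
#' @param traces `n_cells`, `frame_interval_s`, `duration_s`, `tg_time_s`,
#'   `ca_time_s`, `soce_scale` (named per-condition multipliers),
#'   `wave1_amp`, `wave2_amp` (delta-F/F0 units), `tau_s`, `cell_cv`,
#'   `noise_sd`, `background`, `f0`.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       genome = list(), genes = list(), peaks = list(),
                       marks = NULL, mark_signal = list(), motif = list(),
                       conservation = list(), qpcr = list(),
                       traces = list()) {
  cfg <- list(
    seed = as.integer(seed),
    genome = utils::modifyList(
      list(n_chroms = 2L, chrom_length = 1e5), genome),
    genes = utils::modifyList(
      list(n_genes = 24L, exons_per_gene = 3L, exon_len = 600,
           intron_len = 800), genes),
    peaks = utils::modifyList(
      list(n_true_sites = 60L, site_len = 300, jitter_sd = 10,
           fp_per_replicate = 30L, fn_rate = 0.05, n_replicates = 3L,
           true_score_mean = 300, true_score_sd = 60,
           decoy_score_mean = 55, decoy_score_sd = 5), peaks),
    marks = marks %||% c(H3K4me3 = "promoter", H3K27ac = "promoter",
                         H3K4me1 = "intronic", H3K36me3 = "exonic",
                         H3K9me3 = "intergenic", H3K27me3 = "intergenic",
                         CTCF = "intergenic"),
    mark_signal = utils::modifyList(
      list(enriched_mean = 10, background_mean = 1, sd = 0.5,
           n_background_segments = 40L, background_seg_len = 200),
      mark_signal),
    motif = utils::modifyList(
      list(cluster_n = 4L, cluster_span = 130L,
           background_density = 1 / 180), motif),
    conservation = utils::modifyList(
      list(baseline_mean = 0.1, exon_mean = 1.0, element_mean = 1.0,
           sd = 0.08, tile = 25, bump_width = 150, binding_amp = 300),
      conservation),
    qpcr = utils::modifyList(
      list(true_folds = c(Gad1 = 1, Calb2 = 1.4, Stim1_int2_P0 = 35,
                          Stim1_int2_E14 = 100),
           ct_noise_sd = 0.2, n_replicates = 3L, base_input_ct = 24,
           control_percent_input = 0.1, input_fraction = 0.10), qpcr),
    traces = utils::modifyList(
      list(n_cells = 30L, frame_interval_s = 6, duration_s = 600,
           tg_time_s = 100, ca_time_s = 400,
           soce_scale = c(control = 1.0, knockdown = 1.4),
           wave1_amp = 1.2, wave2_amp = 1.0, tau_s = 20, cell_cv = 0.05,
           noise_sd = 0.02, background = 50, f0 = 100), traces)
  )
  validate_sim_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      genome$n_chroms > 0, genome$chrom_length > 0,
      genes$n_genes > 0, genes$exons_per_gene >= 3, genes$exon_len > 0,
      genes$intron_len > 0,
      peaks$n_true_sites > 0, peaks$site_len > 0, peaks$jitter_sd >= 0,
      peaks$fp_per_replicate >= 0, peaks$n_replicates >= 2,
      peaks$fn_rate >= 0, peaks$fn_rate < 1,
      motif$cluster_n >= 0, motif$cluster_span > 0,
      motif$background_density > 0,
      qpcr$ct_noise_sd >= 0, qpcr$n_replicates > 0,
      traces$n_cells > 0, traces$frame_interval_s > 0,
      traces$duration_s %% traces$frame_interval_s == 0,
      traces$tg_time_s < traces$ca_time_s,
      traces$ca_time_s < traces$duration_s
    )
    if (any(qpcr$true_folds <= 0)) {
      stop("qpcr true_folds must be > 0", call. = FALSE)
    }
  })
  structure(cfg, class = "sim_config")
}

sub_seed <- function(seed, k) (as.numeric(seed) * 1009 + k) %% 2147483647

with_substream <- function(cfg, k, code) {
  withr::with_seed(as.integer(sub_seed(cfg$seed, k)), code)
}

#' Simulate gene models and genomic sequence
#'
#' Lays out non-overlapping genes with uniform-random A/C/G/T sequence.
#' Genes are placed with generous intergenic gaps (>= 2.6 kb) and
#' chromosome-end margins so that planted binding-site categories are
#' geometrically unambiguous. Errors if the requested genes do not fit.
#'
#' @param cfg A [sim_config()] object.
#' @return A list: `genes` (gene-model tibble as from
#'   [read_gene_models()]), `sequence` (named character vector),
#'   `introns` (flat intron table).
#' @export
sim_annotation <- function(cfg) {
  g <- cfg$genes
  footprint <- g$exons_per_gene * g$exon_len +
    (g$exons_per_gene - 1) * g$intron_len
  margin <- 3000
  min_gap <- 2600
  per_chrom <- split(seq_len(g$n_genes),
                     rep_len(seq_len(cfg$genome$n_chroms), g$n_genes))
  with_substream(cfg, 1, {
    models <- purrr::imap(per_chrom, function(idx, ci) {
      n <- length(idx)
      chrom <- paste0("chr", ci)
      needed <- 2 * margin + n * footprint + (n + 1) * min_gap
      if (needed > cfg$genome$chrom_length) {
        stop("genes do not fit: need ", needed, " bp on ", chrom,
             " but chrom_length is ", cfg$genome$chrom_length,
             call. = FALSE)
      }
      slack <- cfg$genome$chrom_length - needed
      extra <- diff(c(0, sort(runif(n, 0, slack)), slack))[seq_len(n + 1)]
      gaps <- min_gap + floor(extra)
      starts <- margin + cumsum(gaps[seq_len(n)]) +
        (seq_len(n) - 1) * footprint
      purrr::map(seq_len(n), function(j) {
        gs <- starts[j]
        exon_starts <- gs + (seq_len(g$exons_per_gene) - 1) *
          (g$exon_len + g$intron_len)
        strand <- sample(c("+", "-"), 1)
        tibble::tibble(
          gene_id = sprintf("g%03d", idx[j]),
          transcript_id = sprintf("t%03d", idx[j]),
          chrom = chrom, strand = strand,
          start = gs, end = gs + footprint,
          tss = if (strand == "+") gs else gs + footprint - 1,
          exons = list(tibble::tibble(start = exon_starts,
                                      end = exon_starts + g$exon_len))
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    sequence <- setNames(
      purrr::map_chr(seq_len(cfg$genome$n_chroms), function(ci) {
        paste(sample(c("A", "C", "G", "T"), cfg$genome$chrom_length,
                     replace = TRUE), collapse = "")
      }),
      paste0("chr", seq_len(cfg$genome$n_chroms))
    )
    list(genes = models, sequence = sequence, introns = gene_introns(models))
  })
}

#' Plant disjoint truth binding sites with known categories
#'
#' Places `n_true_sites` sites of `site_len` bp, cycling through the four
#' genomic categories: promoter sites centered within +/- 500 bp of a TSS,
#' exonic sites inside the second exon, intronic sites inside the intron
#' farthest from the TSS, intergenic sites at gap centers. All placements
#' leave > 1 kb margins to the relevant boundaries so midpoint
#' classification recovers the planted category exactly, even under
#' moderate boundary jitter.
#'
#' @param cfg A [sim_config()] object.
#' @param annotation Output of [sim_annotation()].
#' @return A tibble of truth sites: `chrom`, `start`, `end`, `name`,
#'   `category`.
#' @export
sim_truth_sites <- function(cfg, annotation) {
  genes <- annotation$genes
  p <- cfg$peaks
  cats <- rep_len(peak_categories, p$n_true_sites)
  counts <- table(factor(cats, peak_categories))
  gaps <- gene_gaps(genes, cfg$genome$chrom_length)
  capacity <- c(promoter = nrow(genes), exonic = nrow(genes),
                intronic = nrow(genes), intergenic = nrow(gaps))
  short <- counts > capacity[names(counts)]
  if (any(short)) {
    stop("not enough room for planted sites: need ",
         paste(counts[short], names(counts)[short], collapse = ", "),
         call. = FALSE)
  }
  half <- floor(p$site_len / 2)
  with_substream(cfg, 2, {
    hosts <- list(
      promoter = genes[sample.int(nrow(genes), counts[["promoter"]]), ],
      exonic = genes[sample.int(nrow(genes), counts[["exonic"]]), ],
      intronic = genes[sample.int(nrow(genes), counts[["intronic"]]), ],
      intergenic = gaps[sample.int(nrow(gaps), counts[["intergenic"]]), ]
    )
    sites <- purrr::imap(hosts, function(h, cat) {
      if (nrow(h) == 0L) return(NULL)
      mid <- purrr::map_dbl(seq_len(nrow(h)), function(i) {
        switch(cat,
          promoter = h$tss[i] + sample.int(1001L, 1L) - 501L,
          exonic = site_center(h$exons[[i]][2, ], p$site_len),
          intronic = {
            introns <- tibble::tibble(
              start = h$exons[[i]]$end[-nrow(h$exons[[i]])],
              end = h$exons[[i]]$start[-1]
            )
            d <- abs((introns$start + introns$end) / 2 - h$tss[i])
            site_center(introns[which.max(d), ], p$site_len)
          },
          intergenic = floor((h$start[i] + h$end[i]) / 2)
        )
      })
      tibble::tibble(chrom = h$chrom, start = mid - half,
                     end = mid - half + p$site_len, category = cat)
    }) |> dplyr::bind_rows()
    sites |>
      dplyr::arrange(.data$chrom, .data$start) |>
      dplyr::mutate(name = sprintf("site_%03d", dplyr::row_number()),
                    .before = "category")
  })
}

site_center <- function(region, site_len) {
  lo <- region$start[1]
  hi <- region$end[1]
  slack <- (hi - lo) - site_len
  stopifnot(slack >= 0)
  lo + floor(slack / 2) + floor(site_len / 2)
}

gene_gaps <- function(genes, chrom_length) {
  genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      edges <- c(0, d$end, chrom_length)
      starts <- c(0, d$end)
      ends <- c(d$start, chrom_length)
      tibble::tibble(start = starts, end = ends)[ends - starts >= 2600, ]
    }) |>
    dplyr::ungroup()
}

#' Simulate replicate peak calls from planted truth sites
#'
#' Each replicate observes every truth site independently with probability
#' `1 - fn_rate`, with Gaussian boundary jitter, plus `fp_per_replicate`
#' decoy peaks placed disjointly from the truth sites (and from all other
#' decoys, so decoys alone can never form a consensus). Truth peaks get
#' high MACS-style scores; decoys low ones. Ground-truth membership is
#' recorded in the `truth` column.
#'
#' @param cfg A [sim_config()] object.
#' @param truth_sites Output of [sim_truth_sites()].
#' @return A named list of `n_replicates` peak tibbles (`chrom`, `start`,
#'   `end`, `name`, `score`, `truth`).
#' @export
sim_replicate_peaks <- function(cfg, truth_sites) {
  p <- cfg$peaks
  chrom_len <- cfg$genome$chrom_length
  chroms <- unique(truth_sites$chrom)
  with_substream(cfg, 3, {
    # one pool of mutually disjoint decoys, split across replicates
    n_decoys <- p$fp_per_replicate * p$n_replicates
    decoys <- draw_disjoint_decoys(n_decoys, truth_sites, chroms, chrom_len,
                                   p$site_len)
    reps <- purrr::map(seq_len(p$n_replicates), function(r) {
      keep <- runif(nrow(truth_sites)) >= p$fn_rate
      tp <- truth_sites[keep, , drop = FALSE]
      jit <- function(n) round(rnorm(n, 0, p$jitter_sd))
      start <- pmax(0, tp$start + jit(nrow(tp)))
      end <- pmax(start + 1, tp$end + jit(nrow(tp)))
      tp_peaks <- tibble::tibble(
        chrom = tp$chrom, start = start, end = end,
        name = paste0(tp$name, "_r", r),
        score = pmax(50, rnorm(nrow(tp), p$true_score_mean,
                               p$true_score_sd)),
        truth = tp$name
      )
      dec <- decoys[seq((r - 1) * p$fp_per_replicate,
                        length.out = p$fp_per_replicate) + 1, ,
                    drop = FALSE]
      dec_peaks <- tibble::tibble(
        chrom = dec$chrom, start = dec$start, end = dec$end,
        name = sprintf("decoy_r%d_%03d", r, seq_len(nrow(dec))),
        score = pmax(0.1, rnorm(nrow(dec), p$decoy_score_mean,
                                p$decoy_score_sd)),
        truth = NA_character_
      )
      dplyr::bind_rows(tp_peaks, dec_peaks) |>
        dplyr::arrange(.data$chrom, .data$start)
    })
    setNames(reps, paste0("rep", seq_len(p$n_replicates)))
  })
}

draw_disjoint_decoys <- function(n, truth_sites, chroms, chrom_len,
                                 site_len) {
  if (n == 0L) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  taken <- truth_sites[, c("chrom", "start", "end")]
  out <- vector("list", n)
  got <- 0L
  tries <- 0L
  while (got < n && tries < n * 200L) {
    tries <- tries + 1L
    ch <- sample(chroms, 1)
    s <- sample.int(chrom_len - site_len, 1) - 1L
    cand_end <- s + site_len
    tk <- taken[taken$chrom == ch, , drop = FALSE]
    if (nrow(tk) == 0L || all(tk$end <= s | tk$start >= cand_end)) {
      got <- got + 1L
      row <- tibble::tibble(chrom = ch, start = s, end = cand_end)
      out[[got]] <- row
      taken <- dplyr::bind_rows(taken, row)
    }
  }
  if (got < n) stop("could not place disjoint decoy peaks", call. = FALSE)
  dplyr::bind_rows(out)
}

#' Plant an E-box cluster in a sequence window
#'
#' Rewrites the `span`-bp window starting at `position` (0-based) so that
#' it contains exactly `n` non-overlapping CANNTG occurrences: motif
#' placements are drawn with random spacing, the remaining window bases are
#' uniform random, and the whole window is re-sampled until a scan finds
#' exactly `n` hits (accidental E-boxes are thereby excluded).
#'
#' @param seq A single sequence string.
#' @param position 0-based window start.
#' @param n Number of E-boxes to plant.
#' @param span Window length in bp; must satisfy `span >= 6 * n`.
#' @return The modified sequence string.
#' @export
plant_ebox_cluster <- function(seq, position, n = 4, span = 130) {
  stopifnot(length(seq) == 1L, position >= 0)
  if (span < 6 * n) {
    stop("span (", span, ") too small for ", n, " non-overlapping E-boxes",
         call. = FALSE)
  }
  if (position + span > nchar(seq)) {
    stop("window extends beyond the sequence", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(500L)) {
    window <- sample(bases, span, replace = TRUE)
    if (n > 0) {
      free <- span - 6 * n
      cuts <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
      offsets <- cuts + (seq_len(n) - 1L) * 6L  # 0-based, non-overlapping
      for (o in offsets) {
        window[(o + 1):(o + 6)] <- c("C", "A", sample(bases, 2, TRUE),
                                     "T", "G")
      }
    }
    win_str <- paste(window, collapse = "")
    if (nrow(scan_eboxes(win_str)) == n) {
      substr(seq, position + 1, position + span) <- win_str
      return(seq)
    }
  }
  stop("failed to plant an unambiguous E-box cluster", call. = FALSE)
}

#' Simulate chromatin-mark, conservation and binding-score tracks
#'
#' Each mark's enriched segments cover the truth sites of its configured
#' category (plus sparse low-value background segments elsewhere), so
#' category means dominate the genome baseline by construction. The
#' conservation track tiles the genome with baseline noise, elevates exons,
#' and adds a smooth bump (shared with the binding-score track) over the
#' conserved element, so sliding-window conservation and binding profiles
#' co-vary across it.
#'
#' @param cfg A [sim_config()] object.
#' @param annotation Output of [sim_annotation()].
#' @param truth_sites Output of [sim_truth_sites()]; the `element`
#'   attribute (or the first intronic site) hosts the conserved element.
#' @param element Optional one-row tibble overriding the element location.
#' @return A list: `marks` (named list of track tibbles), `conservation`,
#'   `binding` (track tibbles), `element` (the element interval used).
#' @export
sim_tracks <- function(cfg, annotation, truth_sites, element = NULL) {
  ms <- cfg$mark_signal
  cons <- cfg$conservation
  chrom_len <- cfg$genome$chrom_length
  chroms <- names(annotation$sequence)
  if (is.null(element)) {
    intronic <- truth_sites[truth_sites$category == "intronic", ,
                            drop = FALSE]
    stopifnot(nrow(intronic) > 0L)
    element <- intronic[1, , drop = FALSE]
  }
  exons <- gene_exons(annotation$genes)
  with_substream(cfg, 4, {
    marks <- purrr::imap(as.list(cfg$marks), function(cat, mark) {
      enriched <- truth_sites[truth_sites$category == cat, , drop = FALSE]
      seg <- tibble::tibble(
        chrom = enriched$chrom, start = enriched$start, end = enriched$end,
        value = abs(rnorm(nrow(enriched), ms$enriched_mean, ms$sd))
      )
      bg <- draw_disjoint_decoys(ms$n_background_segments,
                                 dplyr::bind_rows(
                                   truth_sites[, c("chrom", "start", "end")],
                                   seg[, c("chrom", "start", "end")]
                                 ),
                                 chroms, chrom_len, ms$background_seg_len)
      bg$value <- abs(rnorm(nrow(bg), ms$background_mean, ms$sd))
      dplyr::bind_rows(seg, bg) |>
        dplyr::arrange(.data$chrom, .data$start)
    })
    elem_mid <- floor((element$start[1] + element$end[1]) / 2)
    bump <- function(pos, chrom) {
      if (chrom != element$chrom[1]) return(rep(0, length(pos)))
      exp(-(pos - elem_mid)^2 / (2 * cons$bump_width^2))
    }
    conservation <- purrr::map(chroms, function(ch) {
      starts <- seq(0, chrom_len - cons$tile, by = cons$tile)
      mids <- starts + cons$tile / 2
      ex <- exons[exons$chrom == ch, , drop = FALSE]
      in_exon <- purrr::map_lgl(mids, function(m) {
        any(ex$start <= m & m < ex$end)
      })
      base <- ifelse(in_exon, cons$exon_mean, cons$baseline_mean)
      value <- base + (cons$element_mean - cons$baseline_mean) *
        bump(mids, ch) + rnorm(length(mids), 0, cons$sd)
      tibble::tibble(chrom = ch, start = starts, end = starts + cons$tile,
                     value = value)
    }) |> dplyr::bind_rows()
    binding <- {
      half_span <- 400
      starts <- seq(elem_mid - half_span, elem_mid + half_span - cons$tile,
                    by = cons$tile)
      mids <- starts + cons$tile / 2
      tibble::tibble(
        chrom = element$chrom[1], start = starts, end = starts + cons$tile,
        value = pmax(0, cons$binding_amp *
                       bump(mids, element$chrom[1]) +
                       rnorm(length(mids), 0, cons$binding_amp * 0.02))
      )
    }
    list(marks = marks, conservation = conservation, binding = binding,
         element = element)
  })
}

#' Simulate a ChIP-qPCR Ct table from known fold enrichments
#'
#' Inverts the percent-input arithmetic: for each amplicon the input Ct
#' sits at `base_input_ct`; the control-antibody Ct is placed so the
#' control recovers `control_percent_input` percent of input; the
#' target-antibody Ct is the control Ct minus `log2(true_fold)`. Gaussian
#' noise of `ct_noise_sd` cycles is added per replicate, so at zero noise
#' [fold_enrichment()] returns the planted folds exactly.
#'
#' @param cfg A [sim_config()] object.
#' @return A Ct tibble (see [read_ct_table()]) with attribute
#'   `true_folds`.
#' @export
sim_ct_table <- function(cfg) {
  q <- cfg$qpcr
  if (any(q$true_folds <= 0)) {
    stop("true_folds must be > 0", call. = FALSE)
  }
  with_substream(cfg, 5, {
    rows <- purrr::imap(as.list(q$true_folds), function(fold, amp) {
      adj <- adjust_input_ct(q$base_input_ct, q$input_fraction)
      control_ct <- adj - log2(q$control_percent_input / 100)
      target_ct <- control_ct - log2(fold)
      reps <- seq_len(q$n_replicates)
      noise <- function(n) rnorm(n, 0, q$ct_noise_sd)
      dplyr::bind_rows(
        tibble::tibble(antibody = "input", replicate = reps,
                       ct = q$base_input_ct + noise(q$n_replicates)),
        tibble::tibble(antibody = "target", replicate = reps,
                       ct = target_ct + noise(q$n_replicates)),
        tibble::tibble(antibody = "control", replicate = reps,
                       ct = control_ct + noise(q$n_replicates))
      ) |>
        dplyr::mutate(sample_id = "sim", amplicon = amp, .before = 1)
    })
    out <- dplyr::bind_rows(rows) |>
      dplyr::relocate("antibody", .after = "sample_id") |>
      dplyr::mutate(replicate = as.integer(.data$replicate))
    structure(validate_ct_table(out), true_folds = q$true_folds)
  })
}

#' Simulate two-wave calcium-imaging traces
#'
#' Each cell's normalized signal is a flat baseline of 1 plus two alpha
#' -function waves, `(t/tau) * exp(1 - t/tau)`: ER release at the
#' thapsigargin time and SOCE at the calcium re-addition time, the latter
#' scaled by the per-condition `soce_scale`. Per-cell amplitude
#' variability (`cell_cv`) and per-frame Gaussian noise are added; traces
#' are emitted as raw fluorescence with a known scalar background so the
#' full normalization path is exercised.
#'
#' @param cfg A [sim_config()] object.
#' @return A trace tibble (see [read_traces()]) with attribute
#'   `true_amplitudes` (per-cell planted wave amplitudes).
#' @export
sim_traces <- function(cfg) {
  tr <- cfg$traces
  if (tr$ca_time_s <= tr$tg_time_s) {
    stop("ca_time_s must exceed tg_time_s", call. = FALSE)
  }
  times <- seq(0, tr$duration_s, by = tr$frame_interval_s)
  alpha_wave <- function(t, t0, tau) {
    x <- (t - t0) / tau
    ifelse(t >= t0, x * exp(1 - x), 0)
  }
  with_substream(cfg, 6, {
    cells <- purrr::imap(as.list(tr$soce_scale), function(scale, cond) {
      purrr::map(seq_len(tr$n_cells), function(i) {
        a1 <- tr$wave1_amp * max(0.1, rnorm(1, 1, tr$cell_cv))
        a2 <- tr$wave2_amp * scale * max(0, rnorm(1, 1, tr$cell_cv))
        signal <- 1 + a1 * alpha_wave(times, tr$tg_time_s, tr$tau_s) +
          a2 * alpha_wave(times, tr$ca_time_s, tr$tau_s) +
          rnorm(length(times), 0, tr$noise_sd)
        tibble::tibble(
          time_s = times,
          cell_id = sprintf("%s_c%02d", cond, i),
          condition = cond,
          raw = tr$background + tr$f0 * signal,
          background = tr$background,
          .amp1 = a1, .amp2 = a2
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    truth <- cells |>
      dplyr::distinct(.data$condition, .data$cell_id, .data$.amp1,
                      .data$.amp2) |>
      dplyr::rename(wave1_amp = ".amp1", wave2_amp = ".amp2")
    out <- dplyr::select(cells, -".amp1", -".amp2")
    structure(out, true_amplitudes = truth)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs every generator with deterministic per-artifact sub-streams of
#' `cfg$seed`: annotation and sequence, truth sites, replicate peaks (the
#' conserved intronic element receives its E-box cluster), signal tracks,
#' the qPCR Ct table, and calcium traces. When `dir` is given, all inputs
#' are written in the standard formats ([write_peaks()], [write_track()],
#' [write_gene_models()], [write_fasta()], CSV) together with ground-truth
#' ledgers.
#'
#' @param cfg A [sim_config()] object.
#' @param dir Optional output directory.
#' @return A list with all generated objects and a `ground_truth` list
#'   (truth sites, element, planted folds, planted amplitudes); when `dir`
#'   is given, also `files`, a named vector of written paths.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  annotation <- sim_annotation(cfg)
  truth_sites <- sim_truth_sites(cfg, annotation)
  replicates <- sim_replicate_peaks(cfg, truth_sites)
  intronic <- truth_sites[truth_sites$category == "intronic", , drop = FALSE]
  element <- intronic[1, , drop = FALSE]
  elem_mid <- floor((element$start[1] + element$end[1]) / 2)
  span <- cfg$motif$cluster_span
  seq_ch <- annotation$sequence[[element$chrom[1]]]
  seq_ch <- with_substream(cfg, 7, plant_ebox_cluster(
    seq_ch, elem_mid - floor(span / 2), cfg$motif$cluster_n, span))
  annotation$sequence[[element$chrom[1]]] <- seq_ch
  tracks <- sim_tracks(cfg, annotation, truth_sites, element = element)
  ct <- sim_ct_table(cfg)
  traces <- sim_traces(cfg)
  out <- list(
    config = cfg,
    annotation = annotation,
    truth_sites = truth_sites,
    replicates = replicates,
    tracks = tracks,
    ct_table = ct,
    traces = traces,
    ground_truth = list(
      truth_sites = truth_sites,
      element = element,
      true_folds = attr(ct, "true_folds"),
      true_amplitudes = attr(traces, "true_amplitudes")
    )
  )
  if (!is.null(dir)) {
    out$files <- write_dataset(out, dir)
  }
  out
}

write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  files <- c(
    genome = p("genome.fa"),
    genes = p("genes.bed12"),
    ct = p("qpcr_ct.csv"),
    traces = p("traces.csv"),
    truth_sites = p("truth_sites.bed"),
    conservation = p("conservation.bedGraph"),
    binding = p("binding.bedGraph")
  )
  write_fasta(sim$annotation$sequence, files[["genome"]])
  write_gene_models(sim$annotation$genes, files[["genes"]])
  readr::write_csv(sim$ct_table, files[["ct"]])
  readr::write_csv(sim$traces, files[["traces"]])
  write_peaks(dplyr::mutate(sim$truth_sites, score = 0), files[["truth_sites"]])
  write_track(sim$tracks$conservation, files[["conservation"]])
  write_track(sim$tracks$binding, files[["binding"]])
  for (r in names(sim$replicates)) {
    f <- p(paste0("peaks_", r, ".bed"))
    write_peaks(sim$replicates[[r]], f)
    files[[paste0("peaks_", r)]] <- f
  }
  for (m in names(sim$tracks$marks)) {
    f <- p(paste0("mark_", m, ".bedGraph"))
    write_track(sim$tracks$marks[[m]], f)
    files[[paste0("mark_", m)]] <- f
  }
  files
}
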