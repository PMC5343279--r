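#' Run the full synthetic-to-results demo pipeline
#'
#' Simulates a complete dataset, writes every input in its standard
#' on-disk format, then runs each analysis stage by reading those files
#' back: consensus peak derivation, midpoint annotation, chromatin-context
#' scoring, E-box cluster enrichment, sliding-window
#' conservation/binding profiling, ChIP-qPCR enrichment and SOCE trace
#' quantification. Stage outputs are written under `outdir` and listed in
#' a checksum manifest, so a rerun with the same config is
#' byte-reproducible. Any stage failure aborts with an error naming the
#' stage.
#'
#' @param config A [sim_config()] object; its seed drives every stage.
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "consensus", "annotate", "context", "motif",
#'   "conserve", "qpcr", "soce")`. Later stages read the files earlier
#'   stages wrote, so a subset only works over an existing `outdir`.
#' @param quiet Suppress per-stage messages (default `FALSE`).
#' @return A `pipeline_manifest` tibble (`file`, `md5`, `bytes`) of every
#'   file under `outdir`, with the config attached as an attribute.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = c("simulate", "consensus", "annotate",
                                    "context", "motif", "conserve", "qpcr",
                                    "soce"),
                         quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inputs <- file.path(outdir, "inputs")
  say <- function(...) if (!quiet) message(...)
  run_stage <- function(name, code) {
    if (!name %in% stages) return(invisible(NULL))
    say("[", name, "]")
    tryCatch(code, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  need <- function(path) {
    if (!file.exists(path)) stop("required file missing: ", path,
                                 call. = FALSE)
    path
  }
  out <- function(...) file.path(outdir, ...)

  run_stage("simulate", {
    sim <- simulate_dataset(config, dir = inputs)
    readr::write_csv(sim$ground_truth$truth_sites,
                     out("inputs", "truth_sites.csv"))
    readr::write_csv(
      tibble::tibble(amplicon = names(sim$ground_truth$true_folds),
                     true_fold = unname(sim$ground_truth$true_folds)),
      out("inputs", "true_folds.csv"))
    readr::write_csv(sim$ground_truth$true_amplitudes,
                     out("inputs", "true_amplitudes.csv"))
    writeLines(utils::capture.output(utils::str(unclass(config))),
               out("config.txt"))
  })

  run_stage("consensus", {
    rep_files <- sort(list.files(inputs, "^peaks_rep", full.names = TRUE))
    if (length(rep_files) < 2L) stop("replicate peak files not found")
    peak_sets <- lapply(rep_files, read_peaks)
    names(peak_sets) <- sub("^peaks_", "", sub("\\.bed$", "",
                                               basename(rep_files)))
    cons <- consensus_peaks(peak_sets)
    write_peaks(dplyr::mutate(tibble::as_tibble(cons),
                              name = sprintf("consensus_%03d",
                                             dplyr::row_number()),
                              score = .data$min_score),
                out("consensus.bed"))
    readr::write_tsv(dplyr::select(tibble::as_tibble(cons), -"core"),
                     out("consensus_scores.tsv"))
  })

  run_stage("annotate", {
    cons <- read_peaks(need(out("consensus.bed")))
    genes <- read_gene_models(need(file.path(inputs, "genes.bed12")))
    ann <- annotate_peaks(cons, genes)
    readr::write_tsv(tibble::as_tibble(ann), out("annotations.tsv"))
    readr::write_tsv(category_summary(ann), out("category_summary.tsv"))
    readr::write_tsv(tss_distance_histogram(ann), out("tss_histogram.tsv"))
  })

  run_stage("context", {
    ann <- annotation_from_tsv(need(out("annotations.tsv")))
    mark_files <- sort(list.files(inputs, "^mark_.*\\.bedGraph$",
                                  full.names = TRUE))
    if (length(mark_files) == 0L) stop("mark tracks not found")
    tracks <- lapply(mark_files, read_track)
    names(tracks) <- sub("^mark_", "", sub("\\.bedGraph$", "",
                                           basename(mark_files)))
    genome_size <- config$genome$n_chroms * config$genome$chrom_length
    cm <- context_matrix(ann, tracks, genome_size = genome_size)
    readr::write_tsv(tibble::as_tibble(cm), out("context.tsv"))
  })

  run_stage("motif", {
    genome <- read_fasta(need(file.path(inputs, "genome.fa")))
    genes <- read_gene_models(need(file.path(inputs, "genes.bed12")))
    element <- element_site(need(file.path(inputs, "truth_sites.csv")))
    introns <- gene_introns(genes)
    intron_seqs <- purrr::map_chr(seq_len(nrow(introns)), function(i) {
      substring(genome[[introns$chrom[i]]], introns$start[i] + 1,
                introns$end[i])
    })
    bg <- ebox_density(intron_seqs)
    span <- config$motif$cluster_span
    mid <- floor((element$start + element$end) / 2)
    window_seq <- substring(genome[[element$chrom]],
                            mid - floor(span / 2) + 1,
                            mid - floor(span / 2) + span)
    hits <- scan_eboxes(window_seq)
    readr::write_tsv(
      tibble::tibble(
        window_bp = span, n_eboxes = nrow(hits),
        measured_density = bg$density, bp_per_motif = bg$bp_per_motif,
        configured_density = config$motif$background_density,
        fold_vs_measured = cluster_enrichment(nrow(hits), span, bg$density),
        fold_vs_configured = cluster_enrichment(
          nrow(hits), span, config$motif$background_density)
      ),
      out("motif_summary.tsv"))
  })

  run_stage("conserve", {
    conservation <- read_track(need(file.path(inputs,
                                              "conservation.bedGraph")))
    binding <- read_track(need(file.path(inputs, "binding.bedGraph")))
    genes <- read_gene_models(need(file.path(inputs, "genes.bed12")))
    element <- element_site(need(file.path(inputs, "truth_sites.csv")))
    span <- 550; window <- 50
    mid <- floor((element$start + element$end) / 2)
    lo <- mid - floor(span / 2)
    prof_cons <- sliding_profile(
      track_values(conservation, element$chrom, lo, lo + span),
      window = window, start = lo)
    prof_bind <- sliding_profile(
      track_values(binding, element$chrom, lo, lo + span),
      window = window, start = lo)
    rho <- profile_concordance(prof_cons, prof_bind)
    bg_seed <- as.integer(sub_seed(config$seed, 8))
    exonic <- random_region_profiles(genes, conservation, kind = "exonic",
                                     span = span, window = window,
                                     seed = bg_seed)
    intronic <- random_region_profiles(genes, conservation,
                                       kind = "intronic", span = span,
                                       window = window, seed = bg_seed + 1L)
    profiles <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(prof_cons), profile = "element_conservation"),
      dplyr::mutate(tibble::as_tibble(prof_bind), profile = "element_binding"),
      dplyr::mutate(tibble::as_tibble(exonic$mean_profile),
                    profile = "random_exonic_mean"),
      dplyr::mutate(tibble::as_tibble(intronic$mean_profile),
                    profile = "random_intronic_mean")
    )
    readr::write_tsv(profiles, out("profiles.tsv"))
    readr::write_tsv(
      tibble::tibble(spearman_binding_vs_conservation = rho),
      out("conserve_summary.tsv"))
  })

  run_stage("qpcr", {
    ct <- read_ct_table(need(file.path(inputs, "qpcr_ct.csv")))
    enr <- fold_enrichment(ct, input_fraction = config$qpcr$input_fraction)
    readr::write_csv(tibble::as_tibble(enr), out("enrichment.csv"))
  })

  run_stage("soce", {
    traces <- read_traces(need(file.path(inputs, "traces.csv")))
    met <- soce_metrics(traces, tg_time = config$traces$tg_time_s,
                        ca_time = config$traces$ca_time_s)
    readr::write_csv(tibble::as_tibble(met), out("soce_metrics.csv"))
    summ <- cohort_summary(met)
    readr::write_csv(tibble::as_tibble(summ), out("soce_summary.csv"))
    readr::write_csv(pairwise_ratios(summ), out("soce_ratios.csv"))
  })

  files <- sort(list.files(outdir, recursive = TRUE, full.names = FALSE))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    bytes = file.size(file.path(outdir, files))
  )
  structure(manifest,
            class = c("pipeline_manifest", class(tibble::tibble())),
            config = config)
}

annotation_from_tsv <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  ann$category <- factor(ann$category, peak_categories)
  structure(tibble::as_tibble(ann),
            class = c("peak_annotation", class(tibble::tibble())))
}

element_site <- function(truth_csv) {
  truth <- readr::read_csv(truth_csv, show_col_types = FALSE)
  intronic <- truth[truth$category == "intronic", , drop = FALSE]
  if (nrow(intronic) == 0L) stop("no intronic truth site recorded")
  as.list(intronic[1, ])
}
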