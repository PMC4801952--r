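#' Derive a stage-specific seed from a master seed
#'
#' One master seed fans out to per-stage seeds through a fixed polynomial
#' hash of the stage name, so independent stochastic stages never share a
#' stream and every run is reproducible from a single integer. The result is
#' always a positive 31-bit integer.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483647                       # 2^31 - 1 (prime)
  h <- as.numeric(seed) %% m
  for (u in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + u) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end co-occupancy pipeline with their
#' defaults: 1,000 bp bins, posterior threshold 0.5, 25 kbp smoothing window,
#' 100 shuffle rounds, and the synthetic-genome settings of
#' [sim_genome_config()]. A single master seed fans out to per-stage seeds
#' via [derive_seed()].
#'
#' @param genome_config A [sim_genome_config()].
#' @param peak_config A [peak_call_config()].
#' @param smooth_window Smoothing window in bp for exported enrichment
#'   curves (default 25000).
#' @param n_rounds Shuffle rounds for the co-occupancy null (default 100).
#' @param sororin_efficiency Retention probability of an eligible sororin
#'   site (default 0.8).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_config = NULL,
                            peak_config = peak_call_config(),
                            smooth_window = 25000,
                            n_rounds = 100,
                            sororin_efficiency = 0.8,
                            seed = 1) {
  if (is.null(genome_config)) genome_config <- sim_genome_config(seed = seed)
  stopifnot(inherits(genome_config, "sim_genome_config"),
            inherits(peak_config, "peak_call_config"))
  structure(list(genome_config = genome_config, peak_config = peak_config,
                 smooth_window = smooth_window, n_rounds = n_rounds,
                 sororin_efficiency = sororin_efficiency,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the simulate / call / co-occupancy pipeline
#'
#' Executes the genomics arm end to end on a synthetic genome:
#' 1. simulate replication timing, cohesin sites, early-S and G2 sororin
#'    sites, ChIP and BrdU-DIP tracks with matched controls;
#' 2. call enriched regions on each track with the two-state Poisson HMM;
#' 3. co-occupancy of early-S sororin peaks and of G2 sororin peaks with the
#'    early-pulse replicated regions (placement p-values vs shuffle nulls);
#' 4. common-site bookkeeping between the early-S and G2 sororin peak sets.
#'
#' When `out_dir` is given, all intermediate standard-format files
#' (chromosome sizes, bedGraph tracks, BED peak sets, smoothed enrichment
#' curves) and a JSON report are written. Re-running with the same
#' configuration reproduces the report exactly (all stochastic stages are
#' seeded).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return The report: a list with peak counts, overlap stats, co-occupancy
#'   summaries and configuration echo.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gc_ <- config$genome_config
  gc_$seed <- derive_seed(config$seed, "genome")
  genome <- gc_$genome

  timing <- simulate_timing(gc_)
  cohesin <- simulate_cohesin_sites(gc_)
  sor_early <- simulate_sororin_sites(
    cohesin, timing, t_now = gc_$pulse[2],
    efficiency = config$sororin_efficiency,
    seed = derive_seed(config$seed, "sororin-early"))
  sor_g2 <- simulate_sororin_sites(
    cohesin, timing, t_now = gc_$s_duration,
    efficiency = config$sororin_efficiency,
    seed = derive_seed(config$seed, "sororin-g2"))

  brdu <- simulate_brdu_track(timing, gc_)
  chip_early <- simulate_chip_track(sor_early, gc_, seed_tag = "chip-early")
  chip_g2 <- simulate_chip_track(sor_g2, gc_, seed_tag = "chip-g2")

  peaks_brdu <- call_enriched_regions(brdu$treatment, brdu$control, genome,
                                      config$peak_config)
  peaks_early <- call_enriched_regions(chip_early$treatment,
                                       chip_early$control, genome,
                                       config$peak_config)
  peaks_g2 <- call_enriched_regions(chip_g2$treatment, chip_g2$control,
                                    genome, config$peak_config)

  co_early <- cooccupancy_analysis(peaks_early, peaks_brdu, genome,
                                   n_rounds = config$n_rounds,
                                   seed = derive_seed(config$seed, "co-early"))
  co_g2 <- cooccupancy_analysis(peaks_g2, peaks_brdu, genome,
                                n_rounds = config$n_rounds,
                                seed = derive_seed(config$seed, "co-g2"))
  ov <- overlap_stats(peaks_early, peaks_g2)

  report <- list(
    seed = config$seed,
    n_cohesin_sites = length(cohesin),
    n_sororin_sites_early = length(sor_early),
    n_sororin_sites_g2 = length(sor_g2),
    n_peaks_brdu = length(peaks_brdu),
    n_peaks_sororin_early = length(peaks_early),
    n_peaks_sororin_g2 = length(peaks_g2),
    cooccupancy_early = list(
      frac_sig = co_early$frac_sig, frac_sig_null = co_early$frac_sig_null,
      ks_stat = unname(co_early$ks$statistic), ks_p = co_early$ks$p.value,
      p_quartiles = unname(stats::quantile(co_early$p, c(0.25, 0.5, 0.75)))),
    cooccupancy_g2 = list(
      frac_sig = co_g2$frac_sig, frac_sig_null = co_g2$frac_sig_null,
      ks_stat = unname(co_g2$ks$statistic), ks_p = co_g2$ks$p.value,
      p_quartiles = unname(stats::quantile(co_g2$p, c(0.25, 0.5, 0.75)))),
    overlap_early_vs_g2 = unclass(ov))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genome(genome, file.path(out_dir, "sizes.txt"))
    write_bedgraph(brdu$treatment, file.path(out_dir, "brdu_early.bedgraph"))
    write_bedgraph(brdu$control,
                   file.path(out_dir, "brdu_early_control.bedgraph"))
    write_bedgraph(chip_early$treatment,
                   file.path(out_dir, "sororin_earlyS.bedgraph"))
    write_bedgraph(chip_g2$treatment,
                   file.path(out_dir, "sororin_G2.bedgraph"))
    write_bedgraph(smooth_track(brdu$treatment, config$smooth_window),
                   file.path(out_dir, "brdu_early_smoothed.bedgraph"))
    write_bed(cohesin, file.path(out_dir, "cohesin_sites.bed"))
    write_bed(sor_early, file.path(out_dir, "sororin_sites_earlyS.bed"))
    write_bed(sor_g2, file.path(out_dir, "sororin_sites_G2.bed"))
    write_bed(peaks_brdu, file.path(out_dir, "peaks_brdu_early.bed"))
    write_bed(peaks_early, file.path(out_dir, "peaks_sororin_earlyS.bed"))
    write_bed(peaks_g2, file.path(out_dir, "peaks_sororin_G2.bed"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
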