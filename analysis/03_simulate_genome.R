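#!/usr/bin/env Rscript
# Stage 3: generate the synthetic replication-timing genome.
#
# 3 chromosomes x 10 Mbp with ~1 Mbp replication-timing domains over an
# 8 h S-phase; 2,000 non-overlapping cohesin sites; sororin sites are the
# cohesin sites on DNA already replicated at the sampling time (early S =
# end of the 0-2 h BrdU pulse; G2 = end of S), retained with 80%
# efficiency. Read tracks are Poisson: depth 5 background, 8-fold
# enrichment, with matched flat controls. Everything is written in
# standard formats for stage 4.

suppressPackageStartupMessages(library(cohesindyn))

seed <- 20260926
out <- "results/genome"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_genome_config(seed = derive_seed(seed, "genome"))
timing <- simulate_timing(cfg)
cohesin <- simulate_cohesin_sites(cfg)
sor_early <- simulate_sororin_sites(cohesin, timing, t_now = cfg$pulse[2],
                                    efficiency = 0.8,
                                    seed = derive_seed(seed, "sor-early"))
sor_g2 <- simulate_sororin_sites(cohesin, timing, t_now = cfg$s_duration,
                                 efficiency = 0.8,
                                 seed = derive_seed(seed, "sor-g2"))
brdu <- simulate_brdu_track(timing, cfg)
chip_early <- simulate_chip_track(sor_early, cfg, seed_tag = "chip-early")
chip_g2 <- simulate_chip_track(sor_g2, cfg, seed_tag = "chip-g2")

write_genome(cfg$genome, file.path(out, "sizes.txt"))
# replication timing as a bedGraph (hours into S-phase per bin)
write_bedgraph(binned_track(cfg$genome, cfg$bin_size, timing$times),
               file.path(out, "timing.bedgraph"))
write_bed(cohesin, file.path(out, "cohesin.bed"))
write_bed(sor_early, file.path(out, "sororin_sites_earlyS.bed"))
write_bed(sor_g2, file.path(out, "sororin_sites_G2.bed"))
write_bedgraph(brdu$treatment, file.path(out, "brdu_early.bedgraph"))
write_bedgraph(brdu$control, file.path(out, "brdu_early_control.bedgraph"))
write_bedgraph(chip_early$treatment,
               file.path(out, "sororin_earlyS.bedgraph"))
write_bedgraph(chip_early$control,
               file.path(out, "sororin_earlyS_control.bedgraph"))
write_bedgraph(chip_g2$treatment, file.path(out, "sororin_G2.bedgraph"))
write_bedgraph(chip_g2$control, file.path(out, "sororin_G2_control.bedgraph"))
# 25 kbp smoothed enrichment curve of the BrdU treatment for browsing
write_bedgraph(smooth_track(brdu$treatment, 25000),
               file.path(out, "brdu_early_smoothed.bedgraph"))

truth <- list(
  seed = seed,
  n_cohesin = length(cohesin),
  n_sororin_early = length(sor_early),
  n_sororin_g2 = length(sor_g2),
  early_replicated_bins = sum(unlist(brdu$labeled)),
  pulse_h = cfg$pulse, s_duration_h = cfg$s_duration)
jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message(sprintf(
  "genome: %d cohesin sites; sororin %d (early S) / %d (G2); %d early-replicated bins",
  truth$n_cohesin, truth$n_sororin_early, truth$n_sororin_g2,
  truth$early_replicated_bins))
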