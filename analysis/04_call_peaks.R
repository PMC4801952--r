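#!/usr/bin/env Rscript
# Stage 4: call enriched regions on every track written by stage 3.
#
# Two-state Poisson HMM over 1,000 bp bins with the matched control as a
# smoothed multiplicative exposure; bins with posterior > 0.5 are kept and
# adjacent bins merged. Fitted model parameters are dumped as JSON for
# reproducibility.

suppressPackageStartupMessages(library(cohesindyn))

src <- "results/genome"
out <- "results/peaks"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
genome <- read_genome(file.path(src, "sizes.txt"))
cfg <- peak_call_config()

models <- list()
for (name in c("brdu_early", "sororin_earlyS", "sororin_G2")) {
  treatment <- read_bedgraph(file.path(src, paste0(name, ".bedgraph")),
                             genome, cfg$bin_size)
  control <- read_bedgraph(file.path(src, paste0(name, "_control.bedgraph")),
                           genome, cfg$bin_size)
  peaks <- call_enriched_regions(treatment, control, genome, cfg)
  model <- attr(peaks, "model")
  write_bed(peaks, file.path(out, paste0(name, "_peaks.bed")))
  models[[name]] <- list(
    lambda_bg = model$lambda_bg, lambda_enr = model$lambda_enr,
    trans = model$trans, init = model$init,
    em_iterations = length(model$loglik),
    loglik = model$loglik[length(model$loglik)],
    degenerate = model$degenerate,
    n_peaks = length(peaks),
    peak_bases = sum(GenomicRanges::width(peaks)))
  message(sprintf(
    "%-15s: %4d peaks (%.2f Mbp); lambda %.2f -> %.2f in %d EM iterations",
    name, length(peaks), models[[name]]$peak_bases / 1e6,
    model$lambda_bg, model$lambda_enr, models[[name]]$em_iterations))
}
jsonlite::write_json(models, file.path(out, "hmm_models.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote peak BEDs and ", file.path(out, "hmm_models.json"))
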