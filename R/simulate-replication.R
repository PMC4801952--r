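#' Synthetic genome configuration
#'
#' Settings for the replication-timing genome generator: a small genome with
#' early/mid/late replication-timing domains, cohesin sites placed uniformly
#' genome-wide, sororin sites restricted to already-replicated DNA, and
#' Poisson read tracks for ChIP and BrdU-pulse DIP with matched controls.
#' The default scale (3 chromosomes x 10 Mbp, 2,000 cohesin sites) keeps the
#' full pipeline fast while leaving hundreds of sites per condition.
#'
#' @param genome A [genome_def()]; default 3 chromosomes of 10 Mbp.
#' @param n_cohesin_sites Number of cohesin sites (default 2000).
#' @param site_width Site width in bp (default 500).
#' @param read_depth Mean background reads per bin (default 5).
#' @param enrichment_fold Fold enrichment over background at sites /
#'   replicated bins (default 8), `> 1`.
#' @param pulse Labelling-pulse window in hours `(t_start, t_end)` within
#'   S-phase (default `c(0, 2)`).
#' @param s_duration S-phase duration in hours (default 8).
#' @param domain_mean_length Mean replication-timing domain length in bp
#'   (default 1e6).
#' @param bin_size Bin width in bp (default 1000).
#' @param seed Integer seed.
#' @return A list of class `sim_genome_config`.
#' @export
sim_genome_config <- function(genome = genome_def(paste0("chr", 1:3),
                                                  rep(1e7, 3)),
                              n_cohesin_sites = 2000,
                              site_width = 500,
                              read_depth = 5,
                              enrichment_fold = 8,
                              pulse = c(0, 2),
                              s_duration = 8,
                              domain_mean_length = 1e6,
                              bin_size = 1000,
                              seed = 1) {
  stopifnot(inherits(genome, "genome_def"), n_cohesin_sites >= 0,
            site_width > 0, read_depth > 0, s_duration >= 0,
            domain_mean_length > 0, bin_size > 0)
  if (enrichment_fold <= 1) stop("enrichment_fold must exceed 1")
  if (length(pulse) != 2 || pulse[1] < 0 || pulse[2] > s_duration)
    stop("pulse window must lie within S-phase")
  structure(list(genome = genome, n_cohesin_sites = as.integer(n_cohesin_sites),
                 site_width = site_width, read_depth = read_depth,
                 enrichment_fold = enrichment_fold, pulse = pulse,
                 s_duration = s_duration,
                 domain_mean_length = domain_mean_length,
                 bin_size = bin_size, seed = as.integer(seed)),
            class = "sim_genome_config")
}

#' Simulate a replication-timing profile
#'
#' Chromosomes are partitioned into domains with exponentially distributed
#' lengths (mean `domain_mean_length`, rounded up to whole bins); each domain
#' is assigned a replication time drawn uniformly from `[0, s_duration]`
#' hours. Replication is treated as instantaneous per domain at its assigned
#' time.
#'
#' @param config A [sim_genome_config()].
#' @return An object of class `timing_profile`: named list of per-bin
#'   replication times (hours) plus `s_duration`, `bin_size`, `genome`.
#' @export
simulate_timing <- function(config) {
  stopifnot(inherits(config, "sim_genome_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(config$seed, "timing"))
  nb <- n_bins(config$genome, config$bin_size)
  mean_bins <- max(config$domain_mean_length / config$bin_size, 1)
  times <- lapply(config$genome$chrom, function(ch) {
    n <- nb[[ch]]
    v <- numeric(n)
    pos <- 1L
    while (pos <= n) {
      len <- max(1L, ceiling(stats::rexp(1, rate = 1 / mean_bins)))
      t_dom <- stats::runif(1, 0, config$s_duration)
      v[pos:min(pos + len - 1L, n)] <- t_dom
      pos <- pos + len
    }
    v
  })
  structure(list(times = stats::setNames(times, config$genome$chrom),
                 s_duration = config$s_duration,
                 bin_size = config$bin_size, genome = config$genome),
            class = "timing_profile")
}

#' Simulate a BrdU-pulse DIP read track with matched control
#'
#' Bins whose replication time falls inside the pulse window receive Poisson
#' counts with mean `read_depth * enrichment_fold`; all other bins and the
#' control track everywhere receive Poisson mean `read_depth`.
#'
#' @param timing A [simulate_timing()] profile.
#' @param config A [sim_genome_config()]; its `pulse` window is used unless
#'   `pulse` is supplied.
#' @param pulse Optional `(t_start, t_end)` hours overriding the config.
#' @return List with `treatment` and `control` [binned_track()]s and
#'   `labeled` (per-chromosome logical ground truth).
#' @export
simulate_brdu_track <- function(timing, config, pulse = NULL) {
  stopifnot(inherits(timing, "timing_profile"),
            inherits(config, "sim_genome_config"))
  if (is.null(pulse)) pulse <- config$pulse
  if (pulse[2] <= pulse[1]) stop("empty pulse window")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(config$seed,
                       paste0("brdu", pulse[1], "-", pulse[2])))
  labeled <- lapply(timing$times,
                    function(tt) tt >= pulse[1] & tt <= pulse[2])
  mk <- function(means) lapply(means, function(m) stats::rpois(length(m), m))
  mu_t <- lapply(labeled, function(l)
    ifelse(l, config$read_depth * config$enrichment_fold, config$read_depth))
  mu_c <- lapply(labeled, function(l) rep(config$read_depth, length(l)))
  list(treatment = binned_track(config$genome, config$bin_size, mk(mu_t)),
       control = binned_track(config$genome, config$bin_size, mk(mu_c)),
       labeled = labeled)
}

#' Simulate cohesin binding sites
#'
#' Fixed-width sites with uniformly placed centres, non-overlapping by
#' rejection sampling. The placement is identical across simulated cell-cycle
#' stages (cohesin positions do not move; only sororin occupancy changes).
#'
#' @param config A [sim_genome_config()].
#' @return A sorted `GRanges` of sites.
#' @export
simulate_cohesin_sites <- function(config) {
  stopifnot(inherits(config, "sim_genome_config"))
  n <- config$n_cohesin_sites
  if (n == 0)
    return(interval_set(character(), numeric(), numeric(),
                        genome = config$genome))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(config$seed, "cohesin"))
  w <- config$site_width
  gl <- config$genome$length
  if (n * w >= 0.5 * sum(gl))
    stop("cannot place sites: genome too dense")
  probs <- gl / sum(gl)
  placed <- GenomicRanges::GRanges()
  need <- n
  attempts <- 0L
  while (need > 0L) {
    attempts <- attempts + 1L
    if (attempts > 50L) stop("cannot place all sites after bounded retries")
    m <- need * 2L
    ch <- sample(config$genome$chrom, m, replace = TRUE, prob = probs)
    s0 <- floor(stats::runif(m) * (chrom_length(config$genome, ch) - w + 1))
    cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s0 + 1, s0 + w))
    if (length(placed))
      cand <- cand[GenomicRanges::countOverlaps(cand, placed) == 0]
    # mutual collisions: later-drawn candidate yields to the earlier one
    hits <- GenomicRanges::findOverlaps(cand, cand)
    later <- S4Vectors::queryHits(hits)[S4Vectors::queryHits(hits) >
                                          S4Vectors::subjectHits(hits)]
    if (length(later)) cand <- cand[-unique(later)]
    # candidates are in draw order, so taking a prefix stays uniform
    take <- utils::head(cand, need)
    placed <- c(placed, take)
    need <- need - length(take)
  }
  interval_set(as.character(GenomicRanges::seqnames(placed)),
               GenomicRanges::start(placed) - 1,
               GenomicRanges::end(placed),
               genome = config$genome)
}

#' Simulate sororin sites on replicated DNA
#'
#' Sororin occupies a subset of the cohesin sites: only sites whose bin has
#' replicated by `t_now` are eligible, and each eligible site is retained
#' independently with probability `efficiency`. Sites on unreplicated DNA
#' are never included.
#'
#' @param cohesin Cohesin site `GRanges` (see [simulate_cohesin_sites()]).
#' @param timing A [simulate_timing()] profile.
#' @param t_now Current time in hours into S-phase (use `s_duration` for G2).
#' @param efficiency Retention probability in `[0, 1]` (default 0.8).
#' @param seed Integer seed.
#' @return A sorted `GRanges`, subset of `cohesin`.
#' @export
simulate_sororin_sites <- function(cohesin, timing, t_now, efficiency = 0.8,
                                   seed = 1) {
  stopifnot(inherits(timing, "timing_profile"))
  if (efficiency < 0 || efficiency > 1)
    stop("efficiency must lie in [0, 1]")
  if (!length(cohesin)) return(cohesin)
  ch <- as.character(GenomicRanges::seqnames(cohesin))
  mid0 <- (GenomicRanges::start(cohesin) - 1 +
             GenomicRanges::end(cohesin)) %/% 2
  bin <- mid0 %/% timing$bin_size + 1L
  rep_time <- mapply(function(c_, b_) timing$times[[c_]][b_], ch, bin)
  eligible <- rep_time <= t_now
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  kept <- eligible & (stats::runif(length(cohesin)) < efficiency)
  cohesin[kept]
}

#' Simulate a ChIP read track from point sites with matched control
#'
#' Bins overlapping any site receive Poisson counts with mean
#' `read_depth * enrichment_fold`; all others (and the control everywhere)
#' mean `read_depth`.
#'
#' @param sites Site `GRanges`.
#' @param config A [sim_genome_config()].
#' @param seed_tag Character tag mixed into the seed so different conditions
#'   get independent reads.
#' @return List with `treatment`, `control` [binned_track()]s and `enriched`
#'   (per-chromosome logical ground truth).
#' @export
simulate_chip_track <- function(sites, config, seed_tag = "chip") {
  stopifnot(inherits(config, "sim_genome_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(config$seed, seed_tag))
  nb <- n_bins(config$genome, config$bin_size)
  enriched <- lapply(stats::setNames(config$genome$chrom,
                                     config$genome$chrom),
                     function(ch) logical(nb[[ch]]))
  if (length(sites)) {
    chs <- as.character(GenomicRanges::seqnames(sites))
    first <- (GenomicRanges::start(sites) - 1) %/% config$bin_size + 1L
    last <- (GenomicRanges::end(sites) - 1) %/% config$bin_size + 1L
    for (i in seq_along(sites)) {
      enriched[[chs[i]]][first[i]:last[i]] <- TRUE
    }
  }
  mk <- function(means) lapply(means, function(m) stats::rpois(length(m), m))
  mu_t <- lapply(enriched, function(e)
    ifelse(e, config$read_depth * config$enrichment_fold, config$read_depth))
  mu_c <- lapply(enriched, function(e) rep(config$read_depth, length(e)))
  list(treatment = binned_track(config$genome, config$bin_size, mk(mu_t)),
       control = binned_track(config$genome, config$bin_size, mk(mu_c)),
       enriched = enriched)
}
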