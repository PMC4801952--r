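small_cfg <- function(seed = 1, n_cohesin_sites = 400, ...) {
  sim_genome_config(genome = genome_def(c("chr1", "chr2"), c(5e6, 5e6)),
                    n_cohesin_sites = n_cohesin_sites, seed = seed, ...)
}

test_that("timing profiles are seeded, bounded, and domain-structured", {
  cfg <- small_cfg(seed = 3)
  t1 <- simulate_timing(cfg)
  t2 <- simulate_timing(cfg)
  expect_identical(t1$times, t2$times)
  all_t <- unlist(t1$times)
  expect_true(all(all_t >= 0 & all_t <= cfg$s_duration))

  flat <- simulate_timing(small_cfg(seed = 3, s_duration = 0,
                                    pulse = c(0, 0)))
  expect_true(all(unlist(flat$times) == 0))

  huge <- simulate_timing(small_cfg(seed = 3, domain_mean_length = 1e9))
  for (ch in names(huge$times))
    expect_equal(length(unique(huge$times[[ch]])), 1)
})

test_that("BrdU tracks label exactly the pulse window", {
  cfg <- small_cfg(seed = 5)
  timing <- simulate_timing(cfg)
  allS <- simulate_brdu_track(timing, cfg, pulse = c(0, cfg$s_duration))
  expect_true(all(unlist(allS$labeled)))
  expect_error(simulate_brdu_track(timing, cfg, pulse = c(2, 2)),
               "empty pulse")
  early <- simulate_brdu_track(timing, cfg, pulse = c(0, 2))
  lab <- unlist(early$labeled)
  tt <- unlist(timing$times)
  expect_identical(lab, tt >= 0 & tt <= 2)
  # enriched bins really carry higher counts on average
  cnt <- unlist(early$treatment$values)
  expect_gt(mean(cnt[lab]), 4 * mean(cnt[!lab]))
})

test_that("early-pulse replicated regions are recovered by peak calling", {
  cfg <- small_cfg(seed = 7)
  timing <- simulate_timing(cfg)
  early <- simulate_brdu_track(timing, cfg, pulse = c(0, 2))
  peaks <- call_enriched_regions(early$treatment, early$control,
                                 cfg$genome)
  rf <- recall_fpr(peaks, early$labeled, cfg$genome, cfg$bin_size)
  expect_gte(rf$recall, 0.9)
  expect_lte(rf$fpr, 0.05)

  late <- simulate_brdu_track(timing, cfg, pulse = c(4, 6))
  peaks_late <- call_enriched_regions(late$treatment, late$control,
                                      cfg$genome)
  # disjoint pulse windows label disjoint DNA: called sets barely overlap
  shared <- sum(GenomicRanges::width(
    GenomicRanges::intersect(peaks, peaks_late, ignore.strand = TRUE)))
  expect_lt(shared / sum(GenomicRanges::width(peaks)), 0.05)
})

test_that("cohesin sites are uniform, non-overlapping, and reproducible", {
  cfg <- small_cfg(seed = 9)
  sites <- simulate_cohesin_sites(cfg)
  expect_equal(length(sites), cfg$n_cohesin_sites)
  expect_true(all(GenomicRanges::width(sites) == cfg$site_width))
  expect_equal(sum(GenomicRanges::countOverlaps(sites, sites) > 1), 0)
  expect_identical(sites, simulate_cohesin_sites(cfg))
  none <- simulate_cohesin_sites(small_cfg(seed = 9, n_cohesin_sites = 0))
  expect_equal(length(none), 0)

  # placement is uniform: chromosome share proportional to length, and
  # starts uniform within a chromosome (chi-square GOF over deciles)
  big <- simulate_cohesin_sites(
    sim_genome_config(genome = genome_def(c("c1", "c2", "c3"),
                                          c(1e7, 1e7, 5e6)),
                      n_cohesin_sites = 5000, seed = 23))
  counts <- table(factor(as.character(GenomicRanges::seqnames(big)),
                         levels = c("c1", "c2", "c3")))
  expect_gt(chisq.test(as.numeric(counts),
                       p = c(0.4, 0.4, 0.2))$p.value, 0.001)
  s1 <- GenomicRanges::start(big[GenomicRanges::seqnames(big) == "c1"])
  gof <- chisq.test(as.numeric(table(cut(s1, seq(0, 1e7, by = 1e6)))))
  expect_gt(gof$p.value, 0.001)
})

test_that("sororin occupies only replicated cohesin sites", {
  cfg <- small_cfg(seed = 11)
  timing <- simulate_timing(cfg)
  cohesin <- simulate_cohesin_sites(cfg)
  expect_equal(length(simulate_sororin_sites(cohesin, timing, t_now = 0,
                                             efficiency = 1, seed = 1)), 0)
  allS <- simulate_sororin_sites(cohesin, timing, t_now = cfg$s_duration,
                                 efficiency = 1, seed = 1)
  expect_equal(length(allS), length(cohesin))

  # binomial sanity of the retention thinning at t = 2 h
  mids <- (GenomicRanges::start(cohesin) - 1 +
             GenomicRanges::end(cohesin)) %/% 2
  chs <- as.character(GenomicRanges::seqnames(cohesin))
  rep_t <- mapply(function(c_, b_) timing$times[[c_]][b_],
                  chs, mids %/% cfg$bin_size + 1)
  n_eligible <- sum(rep_t <= 2)
  eff <- 0.8
  got <- length(simulate_sororin_sites(cohesin, timing, t_now = 2,
                                       efficiency = eff, seed = 13))
  sd3 <- 3 * sqrt(n_eligible * eff * (1 - eff))
  expect_lt(abs(got - eff * n_eligible), sd3 + 1e-9)
  expect_error(simulate_sororin_sites(cohesin, timing, 2, efficiency = 2),
               "efficiency")
})

test_that("ChIP tracks recover planted sites and are depth-robust", {
  cfg <- small_cfg(seed = 15, enrichment_fold = 10)
  sites <- simulate_cohesin_sites(cfg)
  chip <- simulate_chip_track(sites, cfg)
  peaks <- call_enriched_regions(chip$treatment, chip$control, cfg$genome)
  rf <- recall_fpr(peaks, chip$enriched, cfg$genome, cfg$bin_size)
  expect_gte(rf$recall, 0.9)
  expect_lte(rf$fpr, 0.05)

  cfg2 <- small_cfg(seed = 15, enrichment_fold = 10, read_depth = 10)
  chip2 <- simulate_chip_track(sites, cfg2)
  peaks2 <- call_enriched_regions(chip2$treatment, chip2$control,
                                  cfg2$genome)
  expect_gte(jaccard_bases(peaks, peaks2), 0.9)

  empty <- simulate_chip_track(sites[0], cfg)
  # without sites, treatment and control share the same flat rate
  expect_lt(abs(mean(unlist(empty$treatment$values)) -
                  mean(unlist(empty$control$values))), 0.3)
})
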