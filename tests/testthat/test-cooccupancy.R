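g100 <- genome_def("chr1", 100)

test_that("nearest distance distinguishes overlap, gap, and ties", {
  q <- interval_set("chr1", 10, 20, genome = g100)
  expect_equal(nearest_distance(q, interval_set("chr1", 15, 30,
                                                genome = g100)), 0)
  expect_equal(nearest_distance(q, interval_set("chr1", 25, 30,
                                                genome = g100)), 5)
  # equidistant neighbours share the distance
  refs <- interval_set("chr1", c(0, 25), c(5, 30), genome = g100)
  expect_equal(nearest_distance(q, refs), 5)
  g2 <- genome_def(c("chr1", "chr2"), c(100, 100))
  expect_error(
    nearest_distance(interval_set("chr2", 0, 10, genome = g2),
                     interval_set("chr1", 0, 10, genome = g2)),
    "undefined distance")
})

test_that("the worked placement example evaluates to 29/91", {
  refs <- interval_set("chr1", 40, 60, genome = g100)
  q <- interval_set("chr1", 45, 55, genome = g100)
  expect_equal(intervalstats_pvalue(q, refs, g100), 29 / 91)
})

test_that("a maximally distant query has p-value one", {
  refs <- interval_set("chr1", 0, 10, genome = g100)
  q <- interval_set("chr1", 90, 100, genome = g100)
  expect_equal(intervalstats_pvalue(q, refs, g100), 1)
})

test_that("analytic p-values equal exhaustive enumeration exactly", {
  set.seed(17)
  for (i in 1:300) {
    L <- sample(50:500, 1)
    ref <- random_ref_instance(L)
    if (!length(ref$start)) next
    w <- sample(1:20, 1)
    qs <- sample(0:(L - w), 1)
    gg <- genome_def("c", L)
    pa <- intervalstats_pvalue(interval_set("c", qs, qs + w, genome = gg),
                               interval_set("c", ref$start, ref$end,
                                            genome = gg), gg)
    pb <- brute_placement_pvalue(qs, qs + w, ref$start, ref$end, L)
    expect_identical(pa, pb)
  }
})

test_that("shuffling keeps chromosome and width, uniform and seeded", {
  g <- genome_def("chr1", 1000)
  qs <- interval_set("chr1", rep(0, 10000), rep(100, 10000), genome = g)
  sh <- shuffle_intervals(qs, g, seed = 5)
  expect_true(all(GenomicRanges::width(sh) == 100))
  starts <- GenomicRanges::start(sh) - 1
  expect_true(all(starts >= 0 & starts <= 900))
  # chi-square GOF against uniform over 10 equal start-position classes
  obs <- table(cut(starts, breaks = seq(-0.5, 900.5, length.out = 11)))
  gof <- chisq.test(as.numeric(obs))
  expect_gt(gof$p.value, 0.001)

  expect_identical(shuffle_intervals(qs[1:50], g, seed = 9),
                   shuffle_intervals(qs[1:50], g, seed = 9))
  full <- interval_set("chr1", 0, 1000, genome = g)
  expect_equal(GenomicRanges::start(shuffle_intervals(full, g, 3)) - 1, 0)
  too_long <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
  expect_error(shuffle_intervals(too_long, g, 1), "longer than")
})

test_that("co-occupancy separates embedded queries from independent ones", {
  g <- genome_def(c("chr1", "chr2"), c(1e6, 1e6))
  set.seed(61)
  # references: 20 sites of 1 kbp per chromosome (2% coverage, so an
  # embedded query can reach p < 0.05)
  rs <- sort(sample(seq(0, 9.8e5, by = 2e4), 20))
  refs <- interval_set(rep(c("chr1", "chr2"), each = 20),
                       rep(rs, 2), rep(rs + 1000, 2), genome = g)
  # embedded queries sit inside references
  qstart <- rep(rs + 250, 2)
  embedded <- interval_set(rep(c("chr1", "chr2"), each = 20),
                           qstart, qstart + 500, genome = g)
  co_emb <- cooccupancy_analysis(embedded, refs, g, n_rounds = 40, seed = 2)
  expect_gt(co_emb$frac_sig, co_emb$frac_sig_null)
  expect_lt(co_emb$ks$p.value, 1e-6)

  # independent queries are calibrated against their own shuffle null
  rnd <- shuffle_intervals(embedded, g, seed = 77)
  co_rnd <- cooccupancy_analysis(rnd, refs, g, n_rounds = 40, seed = 3)
  ks <- suppressWarnings(ks.test(co_rnd$p, co_rnd$null_p))
  expect_lt(unname(ks$statistic), 0.2)

  co0 <- cooccupancy_analysis(embedded, refs, g, n_rounds = 0)
  expect_equal(length(co0$null_p), 0)
  expect_true(is.na(co0$frac_sig_null))
  expect_error(cooccupancy_analysis(embedded[0], refs, g), "empty query")
})

test_that("queries on reference-free chromosomes are excluded and counted", {
  g <- genome_def(c("chr1", "chr2"), c(1e5, 1e5))
  refs <- interval_set("chr1", 1e4, 2e4, genome = g)
  qs <- interval_set(c("chr1", "chr2"), c(12000, 5e4), c(13000, 5.1e4),
                     genome = g)
  co <- cooccupancy_analysis(qs, refs, g, n_rounds = 0)
  expect_equal(co$n_excluded, 1)
  expect_equal(length(co$p), 1)
})

test_that("overlap bookkeeping matches the printed-count construction", {
  g <- genome_def("chr1", 1e7)
  # identical and disjoint sets first
  a <- interval_set("chr1", c(0, 1000), c(100, 1100), genome = g)
  self <- overlap_stats(a, a)
  expect_equal(self$n_common_a, 2)
  expect_equal(self$pct_a_only, 0)
  b <- interval_set("chr1", c(5000, 7000), c(5100, 7100), genome = g)
  expect_equal(overlap_stats(a, b)$pct_a_only, 100)

  # sets realising |A| = 7,671, |B| = 14,811 with 3,869 shared records
  n_a <- 7671; n_b <- 14811; n_shared <- 3869
  step <- 300
  a_start <- (seq_len(n_a) - 1) * step
  b_start <- c(a_start[seq_len(n_shared)] + 50,
               (n_a + seq_len(n_b - n_shared) - 1) * step)
  gg <- genome_def("chr1", (n_a + n_b) * step + 1000)
  A <- interval_set("chr1", a_start, a_start + 100, genome = gg)
  B <- interval_set("chr1", b_start, b_start + 100, genome = gg)
  ov <- overlap_stats(A, B)
  expect_equal(ov$n_common_a, n_shared)
  expect_equal(round(ov$pct_a_only, 1), 49.6)
  # swap symmetry of the corresponding fields
  sw <- overlap_stats(B, A)
  expect_equal(sw$n_a, ov$n_b)
  expect_equal(sw$n_common_a, ov$n_common_b)
  expect_equal(sw$pct_a_only, ov$pct_b_only)
})

test_that("significance fractions are translation invariant", {
  g <- genome_def("chr1", 1e6)
  set.seed(91)
  rs <- sort(sample(seq(1e4, 9e5, by = 1e4), 30))
  refs <- interval_set("chr1", rs, rs + 2000, genome = g)
  qs <- interval_set("chr1", rs + 500, rs + 1500, genome = g)
  co1 <- cooccupancy_analysis(qs, refs, g, n_rounds = 0)
  shift <- 5000
  refs2 <- interval_set("chr1", rs + shift, rs + 2000 + shift, genome = g)
  qs2 <- interval_set("chr1", rs + 500 + shift, rs + 1500 + shift,
                      genome = g)
  co2 <- cooccupancy_analysis(qs2, refs2, g, n_rounds = 0)
  expect_equal(co2$frac_sig, co1$frac_sig)
  expect_equal(co2$p, co1$p)
})
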