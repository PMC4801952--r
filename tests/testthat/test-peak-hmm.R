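test_that("forward-backward posteriors equal exhaustive path enumeration", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(2:10, 1)
    counts <- rpois(n, sample(c(1, 4, 12), n, replace = TRUE))
    trans <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
    scale_b <- runif(n, 0.5, 1.5)
    model <- hmm_model(2, 9, trans,
                       control_scale = list(c = scale_b))
    track <- binned_track(genome_def("c", n * 1000), 1000, list(c = counts))
    post <- posterior_enriched(model, track)$c
    oracle <- brute_hmm_posterior(counts, c(2, 9), trans,
                                  stationary_dist(trans), scale_b)
    expect_lt(max(abs(post - oracle)), 1e-9)
  }
})

test_that("single-bin posterior matches the closed-form Bayes rule", {
  model <- hmm_model(1, 10, matrix(0.5, 2, 2))
  track <- binned_track(genome_def("c", 500), 1000, list(c = 0))
  expect_equal(posterior_enriched(model, track)$c,
               (0.5 * exp(-10)) / (0.5 * exp(-1) + 0.5 * exp(-10)),
               tolerance = 1e-9)
})

test_that("uninformative emissions return the stationary distribution", {
  trans <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  model <- hmm_model(5, 5 * (1 + 1e-12), trans)
  track <- binned_track(genome_def("c", 8000), 1000,
                        list(c = c(3, 7, 5, 0, 2, 9, 4, 5)))
  post <- posterior_enriched(model, track)$c
  expect_equal(post, rep(stationary_dist(trans)[2], 8), tolerance = 1e-6)
})

test_that("EM recovers planted emission rates and never decreases loglik", {
  set.seed(21)
  g <- genome_def("chr1", 5e5)
  truth <- rep(FALSE, 500); truth[101:150] <- TRUE; truth[301:340] <- TRUE
  counts <- rpois(500, ifelse(truth, 20, 2))
  track <- binned_track(g, 1000, list(chr1 = counts))
  model <- fit_hmm_em(track)
  expect_lt(abs(model$lambda_bg - 2) / 2, 0.15)
  expect_lt(abs(model$lambda_enr - 20) / 20, 0.15)
  expect_true(all(diff(model$loglik) > -1e-6))
})

test_that("EM log-likelihood is monotone on arbitrary random data", {
  set.seed(33)
  for (r in 1:20) {
    n <- sample(50:150, 1)
    counts <- rpois(n, runif(1, 1, 8)) +
      rbinom(n, 1, 0.1) * rpois(n, runif(1, 5, 30))
    track <- binned_track(genome_def("c", n * 1000), 1000, list(c = counts))
    model <- fit_hmm_em(track, config = peak_call_config(max_em_iters = 40))
    expect_true(all(diff(model$loglik) > -1e-6))
  }
})

test_that("constant tracks are flagged degenerate and call no peaks", {
  g <- genome_def("chr1", 2e5)
  track <- binned_track(g, 1000, list(chr1 = rep(4, 200)))
  model <- fit_hmm_em(track)
  expect_true(model$degenerate)
  peaks <- call_enriched_regions(track, genome = g)
  expect_equal(length(peaks), 0)
  zero <- binned_track(g, 1000, list(chr1 = rep(0, 200)))
  expect_error(fit_hmm_em(zero), "no signal")
  bad <- binned_track(g, 1000, list(chr1 = c(rep(1, 199), NaN)))
  expect_error(fit_hmm_em(bad), "NaN")
})

test_that("peak calling applies a strict threshold and merges runs", {
  g <- genome_def("chr1", 4000)
  cfg <- peak_call_config(posterior_threshold = 0.5, bin_size = 1000)
  expect_equal(length(call_peaks(list(chr1 = rep(0.5, 4)), g, cfg)), 0)
  pk <- call_peaks(list(chr1 = c(0.9, 0.9, 0.1, 0.8)), g, cfg)
  expect_equal(GenomicRanges::start(pk) - 1, c(0, 3000))
  expect_equal(GenomicRanges::end(pk), c(2000, 4000))
  expect_error(call_peaks(list(chr1 = c(0.5, 1.2, 0, 0)), g, cfg),
               "\\[0, 1\\]")
  expect_error(peak_call_config(posterior_threshold = 1), "between 0 and 1")
})

test_that("calls are invariant under relabeling of the hidden states", {
  set.seed(41)
  counts <- rpois(200, 3) + rbinom(200, 1, 0.08) * rpois(200, 25)
  track <- binned_track(genome_def("c", 2e5), 1000, list(c = counts))
  trans <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, 2, byrow = TRUE)
  m1 <- hmm_model(2, 15, trans)
  # swapped labels: state 1 enriched; the relabeled model must give the
  # complementary posterior
  m2 <- list(lambda = c(15, 2), trans = trans[2:1, 2:1],
             init = rev(stationary_dist(trans)))
  p1 <- posterior_enriched(m1, track)$c
  fb <- cohesindyn:::forward_backward(counts, rep(1, 200), m2$lambda,
                                      m2$trans, m2$init)
  expect_equal(p1, fb$gamma[, 1], tolerance = 1e-12)
})

test_that("planted enriched blocks are recovered with high fidelity", {
  set.seed(55)
  recalls <- c(); fprs <- c()
  for (s in 1:3) {
    g <- genome_def("chr1", 1e6)
    truth <- rep(FALSE, 1000)
    truth[sample(1:950, 8)] <- TRUE
    truth <- as.logical(stats::filter(truth, rep(1, 5), sides = 1) > 0)
    truth[is.na(truth)] <- FALSE
    counts <- rpois(1000, ifelse(truth, 20, 2))
    track <- binned_track(g, 1000, list(chr1 = counts))
    peaks <- call_enriched_regions(track, genome = g)
    rf <- recall_fpr(peaks, list(chr1 = truth), g, 1000)
    recalls <- c(recalls, rf$recall); fprs <- c(fprs, rf$fpr)
  }
  expect_true(all(recalls >= 0.9))
  expect_true(all(fprs <= 0.05))
})
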