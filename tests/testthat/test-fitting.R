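noiseless_trace <- function(params, direction, frame_interval = 30,
                            n_frames = 250, diffusive = 0) {
  cfg <- sim_config(params, noise_sd = 0, frame_interval = frame_interval,
                    n_frames = n_frames, diffusive_fraction = diffusive)
  if (direction == "decay") normalize_trace(simulate_ifrap(cfg))
  else normalize_trace(simulate_frap(cfg))
}

test_that("noiseless two-population data is recovered to high precision", {
  truth <- kinetic_params(dS = 0.4, kOff1 = 0.05, kOff2 = 0.0016)
  f <- fit_exponential(noiseless_trace(truth, "decay"), "bi", "decay")
  expect_true(f$converged)
  expect_equal(f$params$dS, truth$dS, tolerance = 1e-6)
  expect_equal(f$params$kOff1, truth$kOff1, tolerance = 1e-6)
  expect_equal(f$params$kOff2, truth$kOff2, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
})

test_that("noiseless one-population data is recovered to high precision", {
  truth <- kinetic_params(dS = 0, kOff1 = 0.05, kOff2 = 1e-7)
  f <- fit_exponential(noiseless_trace(truth, "decay"), "mono", "decay")
  expect_true(f$converged)
  expect_equal(f$params$dS, 1)              # mono convention
  expect_equal(f$params$kOff2, 0.05, tolerance = 1e-6)
})

test_that("recovery-direction fits agree with decay-direction parameters", {
  truth <- kinetic_params(dS = 0.35, kOff1 = 0.08, kOff2 = 0.002)
  f <- fit_exponential(noiseless_trace(truth, "recovery"), "bi", "recovery")
  expect_equal(f$params$dS, truth$dS, tolerance = 1e-5)
  expect_equal(f$params$kOff1, truth$kOff1, tolerance = 1e-5)
})

test_that("constant traces yield a flagged degenerate fit, not an error", {
  flat <- structure(data.frame(t = 0:49, value = rep(1, 50)),
                    class = c("normalized_trace", "data.frame"))
  f <- fit_exponential(flat, "bi", "decay")
  expect_false(f$converged)
  expect_s3_class(f, "fit_result")
  expect_error(fit_exponential(flat[1:5, ], "bi", "decay"), "at least 8")
})

test_that("the two-population fit never does worse than the nested fit", {
  for (s in 1:10) {
    cfg <- preset_sim_config(if (s %% 2) "g2-smc3" else "g1-smc3", seed = s)
    nt <- normalize_trace(simulate_ifrap(cfg))
    m <- fit_exponential(nt, "mono", "decay")
    b <- fit_exponential(nt, "bi", "decay")
    expect_lte(b$rss, m$rss + 1e-12)
  }
})

test_that("model selection prefers the simpler model on equal fits", {
  f1 <- cohesindyn:::new_fit_result("mono", kinetic_params(1, 0.1, 0.1),
                                    rss = 1.0, n_points = 100,
                                    converged = TRUE)
  f2 <- cohesindyn:::new_fit_result("bi", kinetic_params(0.5, 0.2, 0.05),
                                    rss = 1.0, n_points = 100,
                                    converged = TRUE)
  sel <- select_model(f1, f2)
  expect_equal(as.character(sel), "mono")
  expect_equal(attr(sel, "F"), 0)
  f3 <- f2; f3$n_points <- 60
  expect_error(select_model(f1, f3), "different numbers")
})

test_that("model selection separates one- and two-population data", {
  picks_two <- vapply(1:20, function(s) {
    nt <- normalize_trace(simulate_ifrap(preset_sim_config("g2-smc3",
                                                           seed = s)))
    sel <- select_model(fit_exponential(nt, "mono", "decay"),
                        fit_exponential(nt, "bi", "decay"))
    as.character(sel) == "bi"
  }, logical(1))
  picks_one <- vapply(1:20, function(s) {
    nt <- normalize_trace(simulate_ifrap(preset_sim_config("g1-smc3",
                                                           seed = s)))
    sel <- select_model(fit_exponential(nt, "mono", "decay"),
                        fit_exponential(nt, "bi", "decay"))
    as.character(sel) == "mono"
  }, logical(1))
  expect_gte(mean(picks_two), 0.9)
  expect_gte(mean(picks_one), 0.9)
})

test_that("group summaries match closed-form arithmetic", {
  s <- summarize_group(c(0.4, 0.4, 0.4), field = "dS")
  expect_equal(s$mean, 0.4)
  expect_equal(s$sem, 0)
  expect_equal(s$n, 3)

  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  s2 <- summarize_group(x, field = "dS", other = y)
  # Welch statistic recomputed from first principles
  se <- sqrt(var(x) / 4 + var(y) / 4)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(s2$statistic, t_hand, tolerance = 1e-12)
  expect_equal(s2$comparison_p, 2 * pt(abs(t_hand), df_hand,
                                       lower.tail = FALSE),
               tolerance = 1e-12)

  same <- summarize_group(x, field = "dS", other = x)
  expect_equal(same$statistic, 0)
  expect_equal(same$comparison_p, 1)

  sw <- summarize_group(x, field = "dS", other = y, test = "wilcoxon")
  expect_true(sw$comparison_p > 0 && sw$comparison_p <= 1)
  expect_error(summarize_group(c(1), field = "dS"), "at least 2")
})

test_that("fit tables expose per-cell parameters in reporting units", {
  fits <- lapply(1:3, function(s) {
    nt <- normalize_trace(simulate_ifrap(preset_sim_config("g2-smc3",
                                                           seed = s)))
    fit_exponential(nt, "bi", "decay")
  })
  tab <- fits_table(fits, cell_id = paste0("cell", 1:3))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$tau_fast_min, 1 / tab$kOff1_per_min)
  expect_true(all(tab$dS >= 0 & tab$dS <= 1))
})
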