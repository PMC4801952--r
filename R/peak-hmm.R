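#' Peak-calling configuration
#'
#' Defaults mirror the binned enrichment-calling procedure used throughout
#' the package: 1,000 bp bins, enriched bins kept at posterior probability
#' strictly greater than 0.5, then merged when adjacent.
#'
#' @param posterior_threshold Posterior probability cut-off (strict `>`),
#'   in (0, 1); default 0.5.
#' @param bin_size Bin width in bp; default 1000.
#' @param max_em_iters Maximum Baum-Welch iterations; default 100.
#' @param em_tol Stop when the log-likelihood improves by less than this;
#'   default 1e-6.
#' @return A list of class `peak_call_config`.
#' @export
peak_call_config <- function(posterior_threshold = 0.5, bin_size = 1000,
                             max_em_iters = 100, em_tol = 1e-6) {
  if (posterior_threshold <= 0 || posterior_threshold >= 1)
    stop("posterior_threshold must lie strictly between 0 and 1")
  stopifnot(bin_size > 0, max_em_iters >= 1, em_tol > 0)
  structure(list(posterior_threshold = posterior_threshold,
                 bin_size = bin_size, max_em_iters = max_em_iters,
                 em_tol = em_tol),
            class = "peak_call_config")
}

#' Two-state Poisson HMM parameters
#'
#' Background/enriched hidden Markov model over binned read counts. State 1
#' is background, state 2 enriched (`lambda_enr > lambda_bg` by the
#' relabeling convention). Emissions are Poisson with mean
#' `lambda_state * control_scale_b`, where the per-bin exposure
#' `control_scale_b` is derived from a matched control track (1 everywhere
#' without a control). Initial state probabilities are the stationary
#' distribution of the transition matrix.
#'
#' @param lambda_bg,lambda_enr Poisson means (counts/bin), `lambda_enr >
#'   lambda_bg > 0`.
#' @param trans 2x2 row-stochastic transition matrix.
#' @param init Length-2 initial distribution; default the stationary
#'   distribution of `trans`.
#' @param control_scale Optional named list of per-bin exposure vectors.
#' @return A list of class `hmm_model`.
#' @export
hmm_model <- function(lambda_bg, lambda_enr, trans,
                      init = stationary_dist(trans), control_scale = NULL) {
  stopifnot(lambda_bg > 0, lambda_enr > lambda_bg)
  if (!all(dim(trans) == c(2, 2)) || any(trans < 0) ||
      any(abs(rowSums(trans) - 1) > 1e-8))
    stop("trans must be a 2x2 row-stochastic matrix")
  if (length(init) != 2 || abs(sum(init) - 1) > 1e-8)
    stop("init must be a length-2 distribution")
  structure(list(lambda_bg = lambda_bg, lambda_enr = lambda_enr,
                 trans = trans, init = init, control_scale = control_scale,
                 loglik = numeric(), degenerate = FALSE, converged = NA),
            class = "hmm_model")
}

#' Stationary distribution of a 2x2 transition matrix
#' @param trans Row-stochastic 2x2 matrix.
#' @return Length-2 probability vector.
#' @export
stationary_dist <- function(trans) {
  a <- trans[1, 2]; b <- trans[2, 1]
  if (a + b == 0) return(c(0.5, 0.5))
  c(b, a) / (a + b)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf(
    "hmm_model: lambda_bg = %.4g, lambda_enr = %.4g, self-transitions %.4g/%.4g%s\n",
    x$lambda_bg, x$lambda_enr, x$trans[1, 1], x$trans[2, 2],
    if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# Per-bin exposure from a control track: (control_b + 1) / (mean + 1),
# after smoothing the control over `smooth_bins` bins. The exposure is
# meant to capture broad control variation (mappability, copy number);
# smoothing keeps bin-level Poisson noise in a low-coverage control from
# masquerading as treatment enrichment.
control_exposure <- function(control, pseudocount = 1, smooth_bins = 25) {
  sm <- smooth_track(control, window = smooth_bins * control$bin_size)
  m <- mean(unlist(sm$values, use.names = FALSE))
  lapply(sm$values, function(x) (x + pseudocount) / (m + pseudocount))
}

# Per-chromosome emission likelihood matrix (bins x 2 states), scaled rows.
emission_lik <- function(counts, scale_b, lambda) {
  loge <- cbind(stats::dpois(counts, lambda[1] * scale_b, log = TRUE),
                stats::dpois(counts, lambda[2] * scale_b, log = TRUE))
  mx <- pmax(loge[, 1], loge[, 2])
  list(lik = exp(loge - mx), logmax = mx)
}

# Scaled forward-backward for one chromosome chain.
# Returns gamma (posterior state probs), xi sums (2x2), loglik.
forward_backward <- function(counts, scale_b, lambda, trans, init) {
  n <- length(counts)
  em <- emission_lik(counts, scale_b, lambda)
  B <- em$lik
  if (n == 1L) {
    g <- init * B[1, ]
    ll <- log(sum(g)) + em$logmax
    g <- g / sum(g)
    return(list(gamma = matrix(g, 1, 2), xi = matrix(0, 2, 2), loglik = ll))
  }
  alpha <- matrix(0, n, 2)
  beta <- matrix(0, n, 2)
  cnorm <- numeric(n)
  a <- init * B[1, ]
  cnorm[1] <- sum(a)
  alpha[1, ] <- a / cnorm[1]
  t11 <- trans[1, 1]; t12 <- trans[1, 2]
  t21 <- trans[2, 1]; t22 <- trans[2, 2]
  for (i in 2:n) {
    p1 <- alpha[i - 1, 1] * t11 + alpha[i - 1, 2] * t21
    p2 <- alpha[i - 1, 1] * t12 + alpha[i - 1, 2] * t22
    a1 <- p1 * B[i, 1]; a2 <- p2 * B[i, 2]
    cnorm[i] <- a1 + a2
    alpha[i, 1] <- a1 / cnorm[i]; alpha[i, 2] <- a2 / cnorm[i]
  }
  beta[n, ] <- 1
  for (i in (n - 1):1) {
    b1 <- beta[i + 1, 1] * B[i + 1, 1]
    b2 <- beta[i + 1, 2] * B[i + 1, 2]
    beta[i, 1] <- (t11 * b1 + t12 * b2) / cnorm[i + 1]
    beta[i, 2] <- (t21 * b1 + t22 * b2) / cnorm[i + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  # transition expectations
  xi <- matrix(0, 2, 2)
  if (n > 1) {
    for (j in 1:2) for (k in 1:2) {
      xi[j, k] <- sum(alpha[-n, j] * trans[j, k] * B[-1, k] * beta[-1, k] /
                        cnorm[-1])
    }
  }
  loglik <- sum(log(cnorm)) + sum(em$logmax)
  list(gamma = gamma, xi = xi, loglik = loglik)
}

#' Fit the two-state Poisson HMM by Baum-Welch EM
#'
#' Expectation-maximisation over per-chromosome independent chains. Emission
#' rates are initialised from the 50th and 99th percentile of the non-zero
#' bin counts, self-transitions at 0.99, and the initial state distribution
#' at the stationary distribution of the starting transition matrix; it is
#' then re-estimated as a free EM parameter (shared across chromosome
#' chains), which preserves the monotone-likelihood guarantee. Iterates until
#' the log-likelihood improves by less than `em_tol` or `max_em_iters` is
#' reached; the log-likelihood sequence is non-decreasing. After fitting,
#' states are relabeled so the enriched rate exceeds the background rate. A
#' fit in which the two rates are nearly equal (within 2%) is flagged
#' `degenerate`; downstream [call_enriched_regions()] then reports no peaks.
#'
#' @param treatment A [binned_track()] of counts.
#' @param control Optional matched control [binned_track()]; incorporated as
#'   a multiplicative per-bin exposure `(control_b + 1) / (mean(control) + 1)`.
#' @param config A [peak_call_config()].
#' @return A fitted [hmm_model()] with the per-iteration `loglik` trace.
#' @export
fit_hmm_em <- function(treatment, control = NULL,
                       config = peak_call_config()) {
  stopifnot(inherits(treatment, "binned_track"))
  counts <- treatment$values
  all_counts <- unlist(counts, use.names = FALSE)
  if (anyNA(all_counts) || any(!is.finite(all_counts)))
    stop("NaN or non-finite values in treatment counts")
  if (sum(all_counts) == 0) stop("no signal: treatment track is all zero")
  scale_list <-
    if (is.null(control)) lapply(counts, function(x) rep(1, length(x)))
    else control_exposure(control)
  nz <- all_counts[all_counts > 0]
  lam <- unname(stats::quantile(nz, c(0.5, 0.99), type = 1))
  if (lam[2] <= lam[1]) lam[2] <- lam[1] * 2 + 1
  lambda <- pmax(lam, 1e-3)
  trans <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE)
  init <- stationary_dist(trans)
  n_chains <- sum(lengths(counts) > 0)
  ll_trace <- numeric()
  for (iter in seq_len(config$max_em_iters)) {
    gsum_c <- c(0, 0); gsum_s <- c(0, 0)
    xsum <- matrix(0, 2, 2); g1 <- c(0, 0)
    ll <- 0
    for (ch in names(counts)) {
      if (!length(counts[[ch]])) next
      fb <- forward_backward(counts[[ch]], scale_list[[ch]], lambda, trans,
                             init)
      ll <- ll + fb$loglik
      gsum_c <- gsum_c + colSums(fb$gamma * counts[[ch]])
      gsum_s <- gsum_s + colSums(fb$gamma * scale_list[[ch]])
      xsum <- xsum + fb$xi
      g1 <- g1 + fb$gamma[1, ]
    }
    ll_trace <- c(ll_trace, ll)
    converged <- iter > 1 &&
      abs(ll - ll_trace[iter - 1]) < config$em_tol
    lambda_new <- ifelse(gsum_s > 0, gsum_c / gsum_s, lambda)
    lambda_new <- pmax(lambda_new, 1e-8)
    rs <- rowSums(xsum)
    trans_new <- trans
    for (j in 1:2) if (rs[j] > 0) trans_new[j, ] <- xsum[j, ] / rs[j]
    trans_new <- pmax(trans_new, 1e-8)
    trans_new <- trans_new / rowSums(trans_new)
    lambda <- lambda_new
    trans <- trans_new
    init <- pmax(g1 / n_chains, 1e-12)
    init <- init / sum(init)
    if (converged) break
  }
  # relabel so state 2 is enriched
  if (lambda[1] > lambda[2]) {
    lambda <- rev(lambda)
    trans <- trans[2:1, 2:1]
    init <- rev(init)
  }
  degenerate <- lambda[2] <= lambda[1] * 1.02
  model <- hmm_model(lambda_bg = min(lambda[1], lambda[2] - 1e-9),
                     lambda_enr = lambda[2],
                     trans = trans, init = init,
                     control_scale = scale_list)
  model$loglik <- ll_trace
  model$degenerate <- degenerate
  model$converged <- length(ll_trace) >= 2 &&
    abs(diff(utils::tail(ll_trace, 2))) < config$em_tol
  model
}

#' Posterior probability of enrichment per bin
#'
#' Forward-backward smoothed marginal probability that each bin is in the
#' enriched state given the whole chromosome, computed with per-step scaling.
#'
#' @param model A fitted [hmm_model()].
#' @param treatment The [binned_track()] the model refers to.
#' @return Named list of per-bin probabilities in `[0, 1]`.
#' @export
posterior_enriched <- function(model, treatment) {
  stopifnot(inherits(model, "hmm_model"), inherits(treatment, "binned_track"))
  counts <- treatment$values
  scale_list <- model$control_scale
  if (is.null(scale_list))
    scale_list <- lapply(counts, function(x) rep(1, length(x)))
  if (!setequal(names(scale_list), names(counts)) ||
      !all(vapply(names(counts),
                  function(ch) length(scale_list[[ch]]) ==
                    length(counts[[ch]]), logical(1))))
    stop("model and track are not aligned")
  lambda <- c(model$lambda_bg, model$lambda_enr)
  lapply(stats::setNames(names(counts), names(counts)), function(ch) {
    x <- counts[[ch]]
    if (!length(x)) return(numeric())
    if (length(x) == 1L) {
      l1 <- model$init[1] * stats::dpois(x, lambda[1] * scale_list[[ch]])
      l2 <- model$init[2] * stats::dpois(x, lambda[2] * scale_list[[ch]])
      return(l2 / (l1 + l2))
    }
    fb <- forward_backward(x, scale_list[[ch]], lambda, model$trans,
                           model$init)
    fb$gamma[, 2]
  })
}

#' Call peaks from per-bin posterior probabilities
#'
#' Bins with posterior strictly greater than the threshold are flagged and
#' maximal runs of adjacent flagged bins are merged into peak intervals.
#'
#' @param posteriors Named list of per-bin probabilities (see
#'   [posterior_enriched()]).
#' @param genome A [genome_def()].
#' @param config A [peak_call_config()].
#' @return A sorted `GRanges` of peaks.
#' @export
call_peaks <- function(posteriors, genome, config = peak_call_config()) {
  bad <- unlist(posteriors, use.names = FALSE)
  if (length(bad) && (any(bad < 0) || any(bad > 1)))
    stop("posteriors must lie in [0, 1]")
  flags <- lapply(posteriors, function(p) p > config$posterior_threshold)
  merge_adjacent_bins(flags, genome, config$bin_size)
}

#' One-call enrichment peak calling on a treatment/control track pair
#'
#' Convenience wrapper: fit the HMM, decode posteriors, threshold and merge.
#' Returns an empty set when the fitted model is degenerate (no
#' distinguishable enriched state).
#'
#' @inheritParams fit_hmm_em
#' @param genome The [genome_def()] the tracks are defined on.
#' @return A sorted `GRanges` of peaks, with the fitted model attached as
#'   attribute `model`.
#' @export
call_enriched_regions <- function(treatment, control = NULL, genome,
                                  config = peak_call_config()) {
  model <- fit_hmm_em(treatment, control, config)
  if (isTRUE(model$degenerate)) {
    peaks <- interval_set(character(), numeric(), numeric(), genome = genome)
  } else {
    post <- posterior_enriched(model, treatment)
    peaks <- call_peaks(post, genome, config)
  }
  attr(peaks, "model") <- model
  peaks
}
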