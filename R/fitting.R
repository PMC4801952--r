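#' Fit the exponential exchange model to a normalised trace
#'
#' Nonlinear least squares of the two-population redistribution model (or its
#' single-population special case) to the post-bleach portion of a normalised
#' trace. `direction = "decay"` fits the inverse-FRAP difference form
#' `plateau * ((1 - dS) * exp(-kOff1 t) + dS * exp(-kOff2 t))`;
#' `direction = "recovery"` fits the rising form
#' `plateau * ((1 - dS) * (1 - exp(-kOff1 t)) + dS * (1 - exp(-kOff2 t)))`.
#' Both share the same parameters, so the fitted stable fraction and rates are
#' interchangeable between conventions.
#'
#' Times are taken in seconds from the trace and converted to minutes
#' internally; rates are reported per minute. Parameters are bounded:
#' `dS` in `[0, 1]`, rates in `[1e-7, 10]` per minute, `plateau` in
#' `(0, 2]`. The optimiser (Levenberg-Marquardt, [minpack.lm::nlsLM()]) is
#' started from several points including the single-exponential solution, so
#' a two-population fit can never end worse than the nested one-population
#' fit on the same data. Parameters are reported with `kOff1 >= kOff2`.
#' A single-population fit stores its rate in `kOff2` with `dS = 1`.
#'
#' @param series A [normalize_trace()] result (or data.frame with `t` seconds
#'   and `value`).
#' @param model `"bi"` (two populations) or `"mono"` (one population).
#' @param direction `"decay"` (difference signal, inverse FRAP) or
#'   `"recovery"` (spot FRAP).
#' @param drop_first Drop the first post-bleach frame before fitting
#'   (default `FALSE`). In spot-FRAP data the sub-frame diffusive pool has
#'   already equilibrated by the first acquired frame, which the finite-rate
#'   model cannot represent at `t = 0`.
#' @return An object of class `fit_result`: list with `model`, `params`
#'   ([kinetic_params()]), `rss`, `n_points`, `converged`.
#' @export
fit_exponential <- function(series,
                            model = c("bi", "mono"),
                            direction = c("decay", "recovery"),
                            drop_first = FALSE) {
  model <- match.arg(model)
  direction <- match.arg(direction)
  stopifnot(is.data.frame(series), all(c("t", "value") %in% names(series)))
  post <- series[series$t >= 0, , drop = FALSE]
  if (drop_first && nrow(post) > 1L) post <- post[-1L, , drop = FALSE]
  if (nrow(post) < 8L) stop("need at least 8 post-bleach points to fit")
  if (!all(is.finite(post$value))) stop("non-finite values in trace")
  tm <- post$t / 60           # minutes
  y <- post$value

  if (stats::sd(y) < 1e-12) {
    # no bleach contrast: nothing to fit
    params <- kinetic_params(dS = if (model == "bi") 0.5 else 1,
                             kOff1 = 1e-7, kOff2 = 1e-7,
                             plateau = max(mean(y), 1e-6))
    return(new_fit_result(model, params, rss = sum((y - mean(y))^2),
                          n_points = length(y), converged = FALSE))
  }

  if (model == "mono") {
    fit_mono(tm, y, direction)
  } else {
    fit_bi(tm, y, direction)
  }
}

new_fit_result <- function(model, params, rss, n_points, converged) {
  structure(list(model = model, params = params, rss = rss,
                 n_points = n_points, converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s-exponential): rss = %.4g over %d points%s\n",
              x$model, x$rss, x$n_points,
              if (x$converged) "" else " [not converged]"))
  print(x$params)
  invisible(x)
}

# Rate bounds: floor prevents solver underflow for pools far more stable
# than the acquisition window; ceiling (tau = 0.1 s) admits a sub-frame
# diffusive component while excluding degenerate infinite rates.
rate_lo <- 1e-7
rate_hi <- 600

mono_curve <- function(tm, k, plateau, direction) {
  if (direction == "decay") plateau * exp(-k * tm)
  else plateau * (1 - exp(-k * tm))
}

bi_curve <- function(tm, dS, k1, k2, plateau, direction) {
  if (direction == "decay")
    plateau * ((1 - dS) * exp(-k1 * tm) + dS * exp(-k2 * tm))
  else
    plateau * ((1 - dS) * (1 - exp(-k1 * tm)) + dS * (1 - exp(-k2 * tm)))
}

nls_try <- function(formula, data, start, lower, upper) {
  tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
}

fit_mono <- function(tm, y, direction) {
  span_min <- max(tm[length(tm)], 1e-3)
  # crude rate guesses spanning the acquisition window
  k_starts <- unique(pmin(rate_hi, pmax(rate_lo,
                                        c(2 / span_min, 0.2 / span_min, 20 / span_min))))
  p0 <- max(min(if (direction == "decay") y[1] else y[length(y)], 2), 1e-3)
  best <- NULL
  for (k0 in k_starts) {
    f <- nls_try(y ~ mono_curve(tm, k, plateau, direction),
                 data = list(tm = tm, y = y, direction = direction),
                 start = list(k = k0, plateau = p0),
                 lower = c(rate_lo, 1e-6), upper = c(rate_hi, 2))
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = f, rss = rss)
  }
  if (is.null(best)) {
    params <- kinetic_params(1, 1 / span_min, 1 / span_min, plateau = p0)
    return(new_fit_result("mono", params,
                          rss = sum((y - mono_curve(tm, 1 / span_min, p0,
                                                    direction))^2),
                          n_points = length(y), converged = FALSE))
  }
  cf <- stats::coef(best$fit)
  params <- kinetic_params(dS = 1, kOff1 = cf[["k"]], kOff2 = cf[["k"]],
                           plateau = cf[["plateau"]])
  new_fit_result("mono", params, rss = best$rss, n_points = length(y),
                 converged = isTRUE(best$fit$convInfo$isConv))
}

fit_bi <- function(tm, y, direction) {
  mono <- fit_mono(tm, y, direction)
  km <- mono$params$kOff2
  pm <- mono$params$plateau
  starts <- list(
    list(dS = 0.5, k1 = min(rate_hi, km * 10), k2 = max(rate_lo, km / 10),
         plateau = pm),
    list(dS = 0.3, k1 = min(rate_hi, km * 50), k2 = max(rate_lo, km / 50),
         plateau = pm),
    # nested start: reproduces the mono solution exactly at dS = 1
    list(dS = 1, k1 = min(rate_hi, km * 10), k2 = km, plateau = pm),
    list(dS = 0.8, k1 = min(rate_hi, max(km, 5)), k2 = max(rate_lo, km / 2),
         plateau = pm))
  best <- NULL
  for (s in starts) {
    f <- nls_try(y ~ bi_curve(tm, dS, k1, k2, plateau, direction),
                 data = list(tm = tm, y = y, direction = direction),
                 start = s,
                 lower = c(0, rate_lo, rate_lo, 1e-6),
                 upper = c(1, rate_hi, rate_hi, 2))
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
  }
  # the nested model is a point of the bi parameter space: never do worse
  if (is.null(best) || best$rss > mono$rss) {
    params <- kinetic_params(dS = 1, kOff1 = km, kOff2 = km, plateau = pm)
    return(new_fit_result("bi", params, rss = mono$rss,
                          n_points = length(y), converged = mono$converged))
  }
  cf <- stats::coef(best$fit)
  params <- kinetic_params(dS = cf[["dS"]], kOff1 = cf[["k1"]],
                           kOff2 = cf[["k2"]], plateau = cf[["plateau"]])
  new_fit_result("bi", params, rss = best$rss, n_points = length(y),
                 converged = isTRUE(best$fit$convInfo$isConv))
}

#' Choose between one- and two-population fits (extra sum of squares F-test)
#'
#' Nested-model comparison of a single-exponential and a bi-exponential fit of
#' the same data: `F = ((rss_mono - rss_bi)/2) / (rss_bi/(n - 4))` with 2 and
#' `n - 4` degrees of freedom. The two-population model is preferred only when
#' the improvement is significant at `alpha`; ties, degenerate or
#' non-converged two-population fits fall back to the one-population model.
#'
#' @param mono,bi [fit_exponential()] results for the same data.
#' @param alpha Significance level (default 0.05).
#' @return `"mono"` or `"bi"`, with attributes `F`, `p.value`.
#' @export
select_model <- function(mono, bi, alpha = 0.05) {
  stopifnot(inherits(mono, "fit_result"), inherits(bi, "fit_result"))
  if (mono$n_points != bi$n_points)
    stop("fits compare different numbers of points")
  n <- bi$n_points
  df2 <- n - 4L
  if (df2 <= 0) stop("too few points for the nested F-test")
  if (!bi$converged || bi$rss >= mono$rss) {
    out <- "mono"
    attr(out, "F") <- 0
    attr(out, "p.value") <- 1
    return(out)
  }
  Fstat <- ((mono$rss - bi$rss) / 2) / (bi$rss / df2)
  p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  out <- if (is.finite(p) && p < alpha) "bi" else "mono"
  attr(out, "F") <- Fstat
  attr(out, "p.value") <- p
  out
}

#' Summarise a group of kinetic fits and compare two conditions
#'
#' Extracts one scalar per cell from a list of fits (`dS`, the stable-pool
#' fraction, or a residence time in minutes), and reports mean, standard error
#' of the mean and n. When a second group is given, conditions are compared by
#' a two-sided unpaired Welch t-test (default) or a Mann-Whitney U test.
#'
#' @param fits List of [fit_exponential()] results (or a numeric vector).
#' @param field `"dS"`, `"residence_time_fast"` (`1/kOff1`, minutes) or
#'   `"residence_time_slow"` (`1/kOff2`, minutes).
#' @param other Optional second group (same form as `fits`).
#' @param test `"t"` (unpaired Welch) or `"wilcoxon"` (Mann-Whitney U).
#' @return List with `mean`, `sem`, `n`, `values`, and when `other` is given
#'   `comparison_p` and `statistic`.
#' @export
summarize_group <- function(fits, field = c("dS", "residence_time_fast",
                                            "residence_time_slow"),
                            other = NULL, test = c("t", "wilcoxon")) {
  field <- match.arg(field)
  test <- match.arg(test)
  x <- extract_field(fits, field)
  if (length(x) < 2L) stop("need at least 2 fits per group")
  out <- list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
              n = length(x), values = x)
  if (!is.null(other)) {
    yv <- extract_field(other, field)
    if (length(yv) < 2L) stop("need at least 2 fits per group")
    if (stats::sd(x) == 0 && stats::sd(yv) == 0) {
      # degenerate but well-defined: identical constants compare as equal
      out$statistic <- if (mean(x) == mean(yv)) 0 else Inf
      out$comparison_p <- if (mean(x) == mean(yv)) 1 else 0
    } else if (test == "t") {
      ht <- stats::t.test(x, yv, var.equal = FALSE)
      out$statistic <- unname(ht$statistic)
      out$comparison_p <- ht$p.value
    } else {
      ht <- stats::wilcox.test(x, yv, exact = FALSE)
      out$statistic <- unname(ht$statistic)
      out$comparison_p <- ht$p.value
    }
  }
  out
}

#' Tabulate per-cell fit results
#'
#' @param fits List of [fit_exponential()] results.
#' @param cell_id Optional identifiers (default sequential).
#' @return A data.frame with columns `cell_id`, `model`, `dS`,
#'   `kOff1_per_min`, `kOff2_per_min`, `tau_fast_min`, `tau_slow_min`,
#'   `rss`, `converged`.
#' @export
fits_table <- function(fits, cell_id = seq_along(fits)) {
  stopifnot(length(cell_id) == length(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(cell_id = cell_id[i], model = f$model, dS = f$params$dS,
               kOff1_per_min = f$params$kOff1, kOff2_per_min = f$params$kOff2,
               tau_fast_min = residence_time(f$params$kOff1),
               tau_slow_min = residence_time(f$params$kOff2),
               rss = f$rss, converged = f$converged)
  })
  do.call(rbind, rows)
}

extract_field <- function(fits, field) {
  if (is.numeric(fits)) return(fits)
  vapply(fits, function(f) {
    stopifnot(inherits(f, "fit_result"))
    switch(field,
           dS = f$params$dS,
           residence_time_fast = residence_time(f$params$kOff1),
           residence_time_slow = residence_time(f$params$kOff2))
  }, numeric(1))
}
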