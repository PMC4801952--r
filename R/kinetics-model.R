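#' Two-population chromatin-binding kinetic parameters
#'
#' Container for the parameters of the two-population exponential exchange
#' model used to interpret photobleaching experiments. A fraction `dS` of
#' molecules belongs to a stable, slowly exchanging chromatin-bound pool with
#' off-rate `kOff2`, and the remaining `1 - dS` to a dynamic pool with
#' off-rate `kOff1`. Rates are per minute; residence time is `1/kOff`.
#' `plateau` is the asymptotic level of the redistribution signal
#' (dimensionless, 1 for a fully normalised trace).
#'
#' The fitted-parameter convention is `kOff1 >= kOff2` (fast pool first);
#' [kinetic_params()] enforces it by swapping the rates and replacing `dS`
#' with `1 - dS` when violated.
#'
#' @param dS Stable-pool fraction in `[0, 1]`.
#' @param kOff1 Fast (dynamic-pool) off-rate, 1/min, `> 0`.
#' @param kOff2 Slow (stable-pool) off-rate, 1/min, `> 0`.
#' @param plateau Asymptotic redistribution level (default 1).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(dS = 0.4, kOff1 = 1 / 17.5, kOff2 = 1 / 630)
#' @export
kinetic_params <- function(dS, kOff1, kOff2, plateau = 1) {
  stopifnot(is.numeric(dS), length(dS) == 1L, is.finite(dS),
            is.numeric(kOff1), length(kOff1) == 1L,
            is.numeric(kOff2), length(kOff2) == 1L,
            is.numeric(plateau), length(plateau) == 1L, plateau >= 0)
  if (dS < 0 || dS > 1) stop("dS must lie in [0, 1]")
  if (kOff1 <= 0 || kOff2 <= 0) stop("off-rates must be positive")
  if (kOff1 < kOff2) {
    tmp <- kOff1; kOff1 <- kOff2; kOff2 <- tmp
    dS <- 1 - dS
  }
  structure(list(dS = dS, kOff1 = kOff1, kOff2 = kOff2, plateau = plateau),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "kinetic_params: dS = %.4g, kOff1 = %.4g /min (tau %.4g min), kOff2 = %.4g /min (tau %.4g min), plateau = %.4g\n",
    x$dS, x$kOff1, residence_time(x$kOff1), x$kOff2, residence_time(x$kOff2),
    x$plateau))
  invisible(x)
}

#' Evaluate the redistribution curve of the two-population model
#'
#' Computes `plateau * ((1 - dS) * (1 - exp(-kOff1 * t)) +
#' dS * (1 - exp(-kOff2 * t)))`, the fluorescence redistribution after a
#' photobleach: it rises from 0 at `t = 0` to `plateau` as both pools
#' exchange. The matching inverse-FRAP difference signal is
#' `plateau - eval_redistribution(t, params)` (see [ifrap_decay()]).
#'
#' @param t Time in minutes, `>= 0` (vectorised).
#' @param params A [kinetic_params()] object.
#' @return Redistribution values, monotone non-decreasing in `t` and bounded
#'   by `plateau`.
#' @export
eval_redistribution <- function(t, params) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(t))
  if (any(t < 0)) stop("time must be non-negative")
  params$plateau * ((1 - params$dS) * (1 - exp(-params$kOff1 * t)) +
                      params$dS * (1 - exp(-params$kOff2 * t)))
}

#' Inverse-FRAP decay (difference) signal of the two-population model
#'
#' The unbleached-minus-bleached difference signal measured in inverse FRAP:
#' `plateau - eval_redistribution(t, params)`, which decays from `plateau`
#' towards 0 as the two pools exchange.
#'
#' @inheritParams eval_redistribution
#' @return Decay values, monotone non-increasing in `t`.
#' @export
ifrap_decay <- function(t, params) {
  params$plateau - eval_redistribution(t, params)
}

#' Mean chromatin residence time from an off-rate
#'
#' The mean duration of a single binding event under first-order exchange,
#' `tau = 1 / kOff`.
#'
#' @param kOff Off-rate, 1/min, `> 0` (vectorised).
#' @return Residence time in minutes.
#' @examples
#' residence_time(0.05)       # 20 min
#' residence_time(0.6) * 60   # 100 s
#' @export
residence_time <- function(kOff) {
  stopifnot(is.numeric(kOff))
  if (any(kOff <= 0)) stop("kOff must be positive")
  1 / kOff
}
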