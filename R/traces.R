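#' Raw photobleaching fluorescence trace
#'
#' Per-cell time series of raw intensities measured at the bleached/monitored
#' region of interest, the whole nucleus, and an extracellular background
#' region. The first `n_prebleach` frames precede the bleach.
#'
#' @param t Acquisition times in seconds, strictly increasing.
#' @param roi Raw ROI intensity (arbitrary units), `>= 0`.
#' @param nucleus Raw whole-nucleus intensity, `>= 0`.
#' @param background Raw background intensity, `>= 0`.
#' @param n_prebleach Number of frames acquired before the bleach, `>= 1`.
#' @return An object of class `frap_trace` (a data.frame with attributes).
#' @export
frap_trace <- function(t, roi, nucleus, background, n_prebleach) {
  n <- length(t)
  if (length(roi) != n || length(nucleus) != n || length(background) != n)
    stop("t, roi, nucleus and background must have equal length")
  stopifnot(n_prebleach >= 1, n_prebleach < n)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(roi < 0) || any(nucleus < 0) || any(background < 0))
    stop("intensities must be non-negative")
  structure(
    data.frame(t = t, roi = roi, nucleus = nucleus, background = background),
    n_prebleach = as.integer(n_prebleach),
    class = c("frap_trace", "data.frame"))
}

#' Normalise a photobleaching trace (double-ratio correction)
#'
#' Background-subtracted double-ratio normalisation: the ROI signal is divided
#' by the whole-nucleus signal frame by frame, then scaled so the mean over
#' the pre-bleach frames is exactly 1:
#' \deqn{N(t) = \frac{(roi - bg)/(nuc - bg)}{\langle (roi - bg)/(nuc - bg)
#' \rangle_{pre}}.}
#' Acquisition photobleaching that affects ROI and nucleus by a common
#' multiplicative factor cancels in the ratio. Time is re-zeroed so the first
#' post-bleach frame is `t = 0`; pre-bleach frames carry negative times.
#'
#' @param raw A [frap_trace()].
#' @return A data.frame of class `normalized_trace` with columns `t` (seconds,
#'   first post-bleach frame at 0), `value`, and a `n_prebleach` attribute.
#' @export
normalize_trace <- function(raw) {
  stopifnot(inherits(raw, "frap_trace"))
  npre <- attr(raw, "n_prebleach")
  denom <- raw$nucleus - raw$background
  if (any(denom <= 0))
    stop("degenerate frame: nucleus intensity not above background")
  ratio <- (raw$roi - raw$background) / denom
  pre_mean <- mean(ratio[seq_len(npre)])
  if (!is.finite(pre_mean) || pre_mean == 0)
    stop("degenerate pre-bleach frames: cannot normalise")
  value <- ratio / pre_mean
  t0 <- raw$t[npre + 1L]
  structure(
    data.frame(t = raw$t - t0, value = value),
    n_prebleach = npre,
    class = c("normalized_trace", "data.frame"))
}

#' Read / write a photobleaching trace table
#'
#' Traces are exchanged as delimited text with columns `time_s`, `roi`,
#' `nucleus`, `background`; the number of pre-bleach frames is stored in a
#' `# n_prebleach: <k>` header comment.
#'
#' @param path File path.
#' @return For `read_trace`, a [frap_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  header <- readLines(path, n = 5L)
  m <- regmatches(header, regexec("^#\\s*n_prebleach:\\s*(\\d+)", header))
  npre <- NA_integer_
  for (g in m) if (length(g) == 2L) npre <- as.integer(g[2])
  if (is.na(npre)) stop("trace file lacks '# n_prebleach:' header: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("time_s", "roi", "nucleus", "background")
  if (!all(need %in% names(d)))
    stop("trace file must have columns time_s, roi, nucleus, background")
  frap_trace(d$time_s, d$roi, d$nucleus, d$background, n_prebleach = npre)
}

#' @rdname read_trace
#' @param trace A [frap_trace()] to write.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_prebleach: %d", attr(trace, "n_prebleach")), con)
  d <- data.frame(time_s = trace$t, roi = trace$roi, nucleus = trace$nucleus,
                  background = trace$background)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
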