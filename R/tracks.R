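#' Fixed-width binned genomic track
#'
#' Per-chromosome vectors of counts or scores over fixed-width bins. The
#' last bin of each chromosome may be short (it is clipped to the chromosome
#' end when converted back to intervals).
#'
#' @param genome A [genome_def()].
#' @param bin_size Bin width in bp (default 1000).
#' @param values Optional named list of per-chromosome numeric vectors; when
#'   omitted the track is all zero.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(genome, bin_size = 1000, values = NULL) {
  stopifnot(inherits(genome, "genome_def"), bin_size > 0)
  nbins <- n_bins(genome, bin_size)
  if (is.null(values)) {
    values <- lapply(nbins, numeric)
  } else {
    if (!setequal(names(values), genome$chrom))
      stop("values must be named by the genome's chromosomes")
    values <- values[genome$chrom]
    ok <- vapply(genome$chrom,
                 function(ch) length(values[[ch]]) == nbins[[ch]],
                 logical(1))
    if (!all(ok)) stop("per-chromosome vector length must be ceil(length/bin_size)")
  }
  structure(list(genome = genome, bin_size = bin_size, values = values),
            class = "binned_track")
}

n_bins <- function(genome, bin_size) {
  stats::setNames(as.integer(ceiling(genome$length / bin_size)), genome$chrom)
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d chromosome(s), bin %d bp, %d bins, total %.4g\n",
              nrow(x$genome), x$bin_size,
              sum(lengths(x$values)), sum(unlist(x$values))))
  invisible(x)
}

#' Bin an interval set into per-bin incidence counts
#'
#' Each interval increments by one every bin it overlaps (read-count
#' semantics when the intervals are reads).
#'
#' @param set A `GRanges` (see [interval_set()]).
#' @param genome A [genome_def()].
#' @param bin_size Bin width in bp.
#' @return A [binned_track()] of counts.
#' @export
bin_intervals <- function(set, genome, bin_size = 1000) {
  if (bin_size <= 0) stop("bin_size must be positive")
  track <- binned_track(genome, bin_size)
  if (!length(set)) return(track)
  chroms <- as.character(GenomicRanges::seqnames(set))
  s0 <- GenomicRanges::start(set) - 1          # 0-based
  e0 <- GenomicRanges::end(set)                # half-open end
  len <- chrom_length(genome, chroms)
  if (any(e0 > len)) stop("interval beyond chromosome length")
  first <- s0 %/% bin_size
  last <- (e0 - 1) %/% bin_size
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    v <- track$values[[ch]]
    for (i in idx) {
      b <- (first[i]:last[i]) + 1L
      v[b] <- v[b] + 1
    }
    track$values[[ch]] <- v
  }
  track
}

#' Smooth a binned track with a centred moving mean
#'
#' Moving mean over `window / bin_size` bins, centred on each bin; at the
#' chromosome edges the window is truncated to the available bins.
#'
#' @param track A [binned_track()].
#' @param window Smoothing window in bp; must be a positive multiple of the
#'   track's bin size (default 25000, i.e. k = 25 kbp at 1 kbp bins).
#' @return A smoothed [binned_track()].
#' @export
smooth_track <- function(track, window = 25000) {
  stopifnot(inherits(track, "binned_track"))
  if (window <= 0 || window %% track$bin_size != 0)
    stop("window must be a positive multiple of bin_size")
  w <- window %/% track$bin_size
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  track$values <- lapply(track$values, function(x) {
    n <- length(x)
    if (n == 0L) return(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - hl, 1L)
    hi <- pmin(seq_len(n) + hr, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  track
}

#' Merge runs of flagged adjacent bins into intervals
#'
#' Maximal runs of `TRUE` bins become single intervals in bp coordinates;
#' the final short bin of a chromosome is clipped to the chromosome end.
#'
#' @param flags Named list (by chromosome) of per-bin logical vectors.
#' @param genome A [genome_def()].
#' @param bin_size Bin width in bp.
#' @return A sorted `GRanges` of merged enriched regions.
#' @export
merge_adjacent_bins <- function(flags, genome, bin_size = 1000) {
  stopifnot(inherits(genome, "genome_def"))
  nbins <- n_bins(genome, bin_size)
  if (!setequal(names(flags), genome$chrom))
    stop("flags must be named by the genome's chromosomes")
  out <- list(chrom = character(), start = numeric(), end = numeric())
  for (ch in genome$chrom) {
    f <- flags[[ch]]
    if (length(f) != nbins[[ch]])
      stop("flag vector length mismatch on ", ch)
    if (!any(f)) next
    r <- rle(as.logical(f))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    out$chrom <- c(out$chrom, rep(ch, length(on)))
    out$start <- c(out$start, (starts[on] - 1) * bin_size)
    out$end <- c(out$end, pmin(ends[on] * bin_size,
                               chrom_length(genome, ch)))
  }
  interval_set(out$chrom, out$start, out$end, genome = genome)
}

#' Read / write a binned track as bedGraph
#'
#' `write_bedgraph` writes one row per non-empty run of identical bin values
#' (all bins, including zeros, are representable; zero runs are written too so
#' the round trip is exact). `read_bedgraph` requires records aligned to bin
#' boundaries (as produced by the writer).
#'
#' @param track A [binned_track()].
#' @param path File path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  rows <- lapply(track$genome$chrom, function(ch) {
    x <- track$values[[ch]]
    if (!length(x)) return(NULL)
    r <- rle(x)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    data.frame(chrom = ch,
               start = starts_bin * track$bin_size,
               end = pmin(ends_bin * track$bin_size,
                          chrom_length(track$genome, ch)),
               value = r$values)
  })
  d <- do.call(rbind, rows)
  utils::write.table(format(d, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param genome A [genome_def()] the track is defined on.
#' @param bin_size Bin width in bp.
#' @return For `read_bedgraph`, a [binned_track()].
#' @export
read_bedgraph <- function(path, genome, bin_size = 1000) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- binned_track(genome, bin_size)
  if (!length(gr)) return(track)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1
  e0 <- GenomicRanges::end(gr)
  val <- S4Vectors::mcols(gr)$score
  if (any(s0 %% bin_size != 0))
    stop("bedGraph records must start on bin boundaries")
  for (i in seq_along(gr)) {
    ch <- chroms[i]
    if (!(ch %in% genome$chrom)) stop("unknown chromosome in bedGraph: ", ch)
    b <- (s0[i] %/% bin_size + 1L):((e0[i] - 1) %/% bin_size + 1L)
    track$values[[ch]][b] <- val[i]
  }
  track
}
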