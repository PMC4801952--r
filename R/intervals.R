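#' Construct a sorted genomic interval set
#'
#' Intervals are specified in BED convention (0-based, half-open) and stored
#' as a [GenomicRanges::GRanges] (1-based, closed), sorted by chromosome and
#' start. Overlapping records are allowed. When a genome is supplied,
#' coordinates are validated against chromosome bounds and the seqinfo is
#' attached.
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param score Optional numeric score per record.
#' @param genome Optional [genome_def()] for bounds validation.
#' @return A sorted `GRanges`.
#' @export
interval_set <- function(chrom, start, end, score = NULL, genome = NULL) {
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n)
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("start must be < end (half-open intervals)")
  if (!is.null(genome)) {
    len <- chrom_length(genome, chrom)
    bad <- which(end > len)
    if (length(bad))
      stop("interval end beyond chromosome length at record ", bad[1])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end))
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- genome$chrom
    GenomeInfoDb::seqinfo(gr) <- as_seqinfo(genome)
  }
  GenomicRanges::sort(gr)
}

#' Read a BED file into a sorted interval set
#'
#' Accepts 3+ column BED (chrom, start, end, \[name, score\]). Records are
#' validated (coordinates numeric and non-negative, `start < end`, and within
#' chromosome bounds when a genome is given); violations raise an error
#' naming the offending line. Input is sorted on load.
#'
#' @param path BED file path.
#' @param genome Optional [genome_def()] for validation.
#' @return A sorted `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  if (!length(lineno)) {
    return(interval_set(character(), numeric(), numeric(), genome = genome))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3))
    stop("BED parse error at line ", lineno[which(ncols < 3)[1]],
         ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("BED parse error at line ",
         lineno[which(is.na(start) | is.na(end))[1]],
         ": non-numeric coordinate")
  if (any(start < 0))
    stop("BED parse error at line ", lineno[which(start < 0)[1]],
         ": negative coordinate")
  if (any(start >= end))
    stop("BED parse error at line ", lineno[which(start >= end)[1]],
         ": start >= end")
  score <- NULL
  if (all(ncols >= 5)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    if (!anyNA(sc)) score <- sc
  }
  if (!is.null(genome)) {
    i <- match(chrom, genome$chrom)
    if (anyNA(i))
      stop("BED parse error at line ", lineno[which(is.na(i))[1]],
           ": unknown chromosome ", chrom[which(is.na(i))[1]])
    bad <- which(end > genome$length[i])
    if (length(bad))
      stop("BED parse error at line ", lineno[bad[1]],
           ": end beyond chromosome length")
  }
  interval_set(chrom, start, end, score = score, genome = genome)
}

#' Write an interval set as BED
#'
#' Writes 3-column BED (0-based half-open); when the set carries a `score`
#' metadata column, 5-column BED with a placeholder name is written.
#'
#' @param set A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(set, path) {
  stopifnot(methods::is(set, "GRanges"))
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(set)),
    start = GenomicRanges::start(set) - 1,
    end = GenomicRanges::end(set))
  sc <- S4Vectors::mcols(set)$score
  if (!is.null(sc)) {
    d$name <- "."
    d$score <- sc
  }
  utils::write.table(format(d, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
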