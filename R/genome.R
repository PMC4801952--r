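#' Genome definition (chromosome sizes)
#'
#' An ordered table of chromosome names and lengths. All interval and track
#' operations in the package validate their coordinates against a genome
#' definition; any chromosome-size table is accepted.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp, `> 0`.
#' @return An object of class `genome_def` (a data.frame).
#' @examples
#' genome_def(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_def <- function(chrom, length) {
  stopifnot(base::length(chrom) == base::length(length))
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_def", "data.frame"))
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf("genome_def: %d chromosome(s), %.3g Mbp total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(x)
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$length[i]
}

#' Convert a genome definition to a Seqinfo object
#' @param genome A [genome_def()].
#' @return A [GenomeInfoDb::Seqinfo] with the same chromosomes.
#' @export
as_seqinfo <- function(genome) {
  stopifnot(inherits(genome, "genome_def"))
  GenomeInfoDb::Seqinfo(seqnames = genome$chrom,
                        seqlengths = as.integer(genome$length))
}

#' Read / write a two-column chromosome-sizes file
#' @param path Tab-separated file with columns name, length.
#' @return For `read_genome`, a [genome_def()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  genome_def(d$chrom, d$length)
}

#' @rdname read_genome
#' @param genome A [genome_def()] to write.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "genome_def"))
  utils::write.table(genome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
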