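#' Distance to the nearest reference interval
#'
#' Returns 0 when the query overlaps any reference by at least 1 bp;
#' otherwise the gap in bp between the closest ends (book-ended intervals
#' have gap 0). Queries on chromosomes with no reference have no defined
#' distance and raise an error.
#'
#' @param q Query `GRanges` (vectorised).
#' @param refs Reference `GRanges`.
#' @return Integer distances in bp, one per query.
#' @export
nearest_distance <- function(q, refs) {
  stopifnot(methods::is(q, "GRanges"), methods::is(refs, "GRanges"))
  if (!length(refs)) stop("undefined distance: empty reference set")
  hits <- GenomicRanges::distanceToNearest(q, refs, ignore.strand = TRUE)
  if (length(hits) < length(q)) {
    miss <- setdiff(seq_along(q), S4Vectors::queryHits(hits))
    stop("undefined distance: no reference on chromosome ",
         as.character(GenomicRanges::seqnames(q))[miss[1]])
  }
  d <- integer(length(q))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

# Placement-comparison metric: 0 for an overlap of >= 1 bp, otherwise
# gap + 1 (book-ended intervals count as distance 1, the bedtools-closest
# convention). Using this metric on both sides of the comparison makes the
# analytic placement count agree exactly with exhaustive enumeration.
placement_metric <- function(q, refs) {
  gap <- nearest_distance(q, refs)
  ov <- GenomicRanges::countOverlaps(q, refs, ignore.strand = TRUE) > 0
  ifelse(ov, 0L, gap + 1L)
}

#' Closest-interval placement p-value for a query interval
#'
#' The probability that a uniformly placed interval of the query's width on
#' the query's chromosome lands at least as close to the reference set as the
#' query does: with chromosome length `L`, query width `w` and observed
#' closeness `D` (0 for an overlap, gap + 1 otherwise),
#' `p = #\{s in [0, L - w] : D([s, s + w), refs) <= D_obs\} / (L - w + 1)`.
#' Computed analytically: each reference `[a, b)` contributes the favourable
#' start window `[a - w + 1 - D_obs, b - 1 + D_obs]`; windows are unioned
#' (overlap-deduplicated) before counting. `p` always lies in `(0, 1]`
#' because the observed placement itself is favourable.
#'
#' @param q A single-interval `GRanges` (or use [cooccupancy_analysis()] for
#'   sets).
#' @param refs Reference `GRanges` with at least one interval on the query's
#'   chromosome.
#' @param genome A [genome_def()].
#' @return The placement p-value.
#' @export
intervalstats_pvalue <- function(q, refs, genome) {
  stopifnot(methods::is(q, "GRanges"), length(q) == 1L)
  intervalstats_pvalues(q, refs, genome)
}

#' Vectorised closest-interval p-values
#' @inheritParams intervalstats_pvalue
#' @return One p-value per query interval.
#' @export
intervalstats_pvalues <- function(q, refs, genome) {
  stopifnot(methods::is(q, "GRanges"), methods::is(refs, "GRanges"),
            inherits(genome, "genome_def"))
  qchrom <- as.character(GenomicRanges::seqnames(q))
  L <- chrom_length(genome, qchrom)
  w <- GenomicRanges::width(q)
  if (any(w > L)) stop("query wider than its chromosome")
  D <- placement_metric(q, refs)
  rchrom <- as.character(GenomicRanges::seqnames(refs))
  ra <- GenomicRanges::start(refs) - 1      # 0-based
  rb <- GenomicRanges::end(refs)            # half-open end
  vapply(seq_along(q), function(i) {
    on_chr <- rchrom == qchrom[i]
    lo <- ra[on_chr] - w[i] + 1 - D[i]
    hi <- rb[on_chr] - 1 + D[i]
    count_union(lo, hi, 0, L[i] - w[i]) / (L[i] - w[i] + 1)
  }, numeric(1))
}

# Number of integers in [min_s, max_s] covered by the union of the integer
# windows [lo_i, hi_i]. Windows must be supplied sorted by lo (reference
# sets are sorted, and the windows share a common offset).
count_union <- function(lo, hi, min_s, max_s) {
  lo <- pmax(lo, min_s)
  hi <- pmin(hi, max_s)
  keep <- lo <= hi
  lo <- lo[keep]; hi <- hi[keep]
  if (!length(lo)) return(0)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  prev <- c(-Inf, utils::head(cummax(hi), -1))
  eff_lo <- pmax(lo, prev + 1)
  sum(pmax(0, hi - eff_lo + 1))
}

#' Randomise interval placements (shuffle)
#'
#' Each interval keeps its chromosome and width and receives a new start
#' drawn uniformly from `[0, L - w]`. Shuffled intervals may overlap each
#' other and the original set. Deterministic for a given seed.
#'
#' @param qs `GRanges` to shuffle.
#' @param genome A [genome_def()].
#' @param seed Integer seed.
#' @return A sorted shuffled `GRanges`.
#' @export
shuffle_intervals <- function(qs, genome, seed) {
  stopifnot(methods::is(qs, "GRanges"), inherits(genome, "genome_def"))
  chroms <- as.character(GenomicRanges::seqnames(qs))
  L <- chrom_length(genome, chroms)
  w <- GenomicRanges::width(qs)
  if (any(w > L)) stop("interval longer than its chromosome")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  s0 <- floor(stats::runif(length(qs)) * (L - w + 1))
  interval_set(chroms, s0, s0 + w, genome = genome)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Co-occupancy analysis of a query peak set against a reference set
#'
#' Per-query closest-interval placement p-values, pooled null p-values from
#' `n_rounds` random re-placements of the queries, and summary fractions of
#' significant queries. Queries on chromosomes carrying no reference interval
#' are excluded from the p-value computation and counted.
#'
#' @param qs Query `GRanges` (e.g. ChIP peaks).
#' @param refs Reference `GRanges` (e.g. replicated regions).
#' @param genome A [genome_def()].
#' @param n_rounds Shuffle rounds for the null (default 100); 0 for an
#'   observed-only result.
#' @param seed Integer seed for the shuffles.
#' @param sig_level Threshold used for the `frac_sig` summaries (default
#'   0.05).
#' @return An object of class `cooccupancy_result`: list with `p` (observed
#'   per-query p-values), `distance` (bp to nearest reference), `null_p`
#'   (pooled shuffled p-values), `frac_sig`, `frac_sig_null`, `n_rounds`,
#'   `n_excluded`, `ks` (one-sided Kolmogorov-Smirnov test of observed vs
#'   null p-values, alternative: observed stochastically smaller).
#' @export
cooccupancy_analysis <- function(qs, refs, genome, n_rounds = 100, seed = 1,
                                 sig_level = 0.05) {
  if (!length(qs)) stop("empty query set")
  if (!length(refs)) stop("empty reference set")
  ref_chroms <- unique(as.character(GenomicRanges::seqnames(refs)))
  qchrom <- as.character(GenomicRanges::seqnames(qs))
  usable <- qchrom %in% ref_chroms
  n_excluded <- sum(!usable)
  qs_use <- qs[usable]
  if (!length(qs_use)) stop("no query lies on a chromosome with references")
  p_obs <- intervalstats_pvalues(qs_use, refs, genome)
  d_obs <- nearest_distance(qs_use, refs)
  null_p <- numeric()
  if (n_rounds > 0) {
    null_p <- unlist(lapply(seq_len(n_rounds), function(r) {
      sh <- shuffle_intervals(qs_use, genome,
                              seed = derive_seed(seed, paste0("shuffle", r)))
      intervalstats_pvalues(sh, refs, genome)
    }), use.names = FALSE)
  }
  ks <- NULL
  if (length(null_p)) {
    ks <- suppressWarnings(
      stats::ks.test(p_obs, null_p, alternative = "greater"))
  }
  structure(list(
    p = p_obs, distance = d_obs, null_p = null_p,
    frac_sig = mean(p_obs < sig_level),
    frac_sig_null = if (length(null_p)) mean(null_p < sig_level) else NA_real_,
    n_rounds = n_rounds, n_excluded = n_excluded, sig_level = sig_level,
    ks = ks), class = "cooccupancy_result")
}

#' @export
print.cooccupancy_result <- function(x, ...) {
  cat(sprintf(
    "cooccupancy_result: %d queries (%d excluded), frac p<%.3g = %.3f (null %.3f, %d rounds)\n",
    length(x$p), x$n_excluded, x$sig_level, x$frac_sig,
    x$frac_sig_null, x$n_rounds))
  if (!is.null(x$ks))
    cat(sprintf("  one-sided KS vs null: D = %.4f, p = %.3g\n",
                unname(x$ks$statistic), x$ks$p.value))
  invisible(x)
}

#' Common-site bookkeeping between two peak sets
#'
#' Counts of records in each set that overlap (by at least 1 bp) at least one
#' record of the other set, and the percentages unique to each set.
#'
#' @param a,b Sorted `GRanges` peak sets.
#' @return List of class `overlap_stats` with `n_a`, `n_b`, `n_common_a`,
#'   `n_common_b`, `pct_a_only`, `pct_b_only`.
#' @export
overlap_stats <- function(a, b) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"))
  n_common_a <- sum(GenomicRanges::countOverlaps(a, b,
                                                 ignore.strand = TRUE) > 0)
  n_common_b <- sum(GenomicRanges::countOverlaps(b, a,
                                                 ignore.strand = TRUE) > 0)
  structure(list(
    n_a = length(a), n_b = length(b),
    n_common_a = n_common_a, n_common_b = n_common_b,
    pct_a_only = if (length(a)) 100 * (1 - n_common_a / length(a)) else NA_real_,
    pct_b_only = if (length(b)) 100 * (1 - n_common_b / length(b)) else NA_real_),
    class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "overlap_stats: |A| = %d (%.1f%% A-only), |B| = %d (%.1f%% B-only), common A = %d, common B = %d\n",
    x$n_a, x$pct_a_only, x$n_b, x$pct_b_only, x$n_common_a, x$n_common_b))
  invisible(x)
}
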