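# Independent oracles used across tests. These deliberately re-derive
# quantities by enumeration / closed form, not by calling the package's
# analytic code paths.

# Exhaustive-placement p-value: slide a window of width w over [0, L - w]
# and count placements at least as close to the references as the observed
# start. Closeness metric: 0 for an overlap of >= 1 bp, otherwise gap + 1.
brute_placement_pvalue <- function(q_start, q_end, ref_start, ref_end, L) {
  w <- q_end - q_start
  metric <- function(s) {
    ov <- any(s < ref_end & s + w > ref_start)
    if (ov) return(0)
    min(pmax(ref_start - (s + w), s - ref_end)) + 1
  }
  d_obs <- metric(q_start)
  favourable <- sum(vapply(0:(L - w), function(s) metric(s) <= d_obs,
                           logical(1)))
  favourable / (L - w + 1)
}

# Exhaustive posterior over all 2^n hidden-state paths of a two-state
# Poisson HMM (state 2 = enriched).
brute_hmm_posterior <- function(counts, lambda, trans, init,
                                scale_b = rep(1, length(counts))) {
  n <- length(counts)
  states <- as.matrix(expand.grid(rep(list(1:2), n)))
  pr <- apply(states, 1, function(st) {
    p <- init[st[1]] * stats::dpois(counts[1], lambda[st[1]] * scale_b[1])
    if (n > 1) for (i in 2:n) {
      p <- p * trans[st[i - 1], st[i]] *
        stats::dpois(counts[i], lambda[st[i]] * scale_b[i])
    }
    p
  })
  vapply(1:n, function(i) sum(pr[states[, i] == 2]) / sum(pr), numeric(1))
}

# Fraction of ground-truth bases recovered by calls, and fraction of
# non-truth bases called, both at bin/base level on one genome.
recall_fpr <- function(calls, truth_flags, genome, bin_size) {
  called <- lapply(stats::setNames(genome$chrom, genome$chrom), function(ch) {
    n <- ceiling(genome$length[match(ch, genome$chrom)] / bin_size)
    v <- logical(n)
    on_ch <- calls[as.character(GenomicRanges::seqnames(calls)) == ch]
    if (length(on_ch)) for (i in seq_along(on_ch)) {
      b <- ((GenomicRanges::start(on_ch[i]) - 1) %/% bin_size + 1):
        ((GenomicRanges::end(on_ch[i]) - 1) %/% bin_size + 1)
      v[b] <- TRUE
    }
    v
  })
  called <- unlist(called, use.names = FALSE)
  truth <- unlist(truth_flags[genome$chrom], use.names = FALSE)
  list(recall = sum(called & truth) / max(sum(truth), 1),
       fpr = sum(called & !truth) / max(sum(!truth), 1))
}

# Base-level Jaccard index of two interval sets.
jaccard_bases <- function(a, b) {
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(a, b,
                                                             ignore.strand = TRUE)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(a, b,
                                                       ignore.strand = TRUE)))
  if (uni == 0) return(1)
  inter / uni
}

# Tiny random reference set on one chromosome for p-value oracle sweeps.
random_ref_instance <- function(L) {
  nr <- sample(1:5, 1)
  rs <- sort(sample(0:(L - 2), nr))
  re <- pmin(rs + sample(1:30, nr, replace = TRUE), L)
  ok <- rs < re
  list(start = rs[ok], end = re[ok])
}
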