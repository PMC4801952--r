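---
title: "Models and methods: chromatin-binding kinetics and replication-coupled co-occupancy"
author: "cohesindyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesindyn)
```

This package implements two quantitative analyses of cohesin and sororin
chromatin dynamics, together with synthetic generators for both data
modalities so every stage can be exercised end to end without external
data: (1) photobleaching (iFRAP/FRAP) kinetics interpreted with a
two-population chromatin-exchange model, and (2) genome-wide co-occupancy
of protein-binding peaks with replicated DNA, via binned HMM enrichment
calling, analytic closest-interval placement p-values, and
randomised-placement nulls.

## 1. The two-population exchange model

Fluorescent cohesin redistributes after a photobleach according to

$$a(t) \;=\; P\left[(1-d_S)\,(1-e^{-k_{off,1} t}) \;+\;
d_S\,(1-e^{-k_{off,2} t})\right],$$

where $d_S \in [0,1]$ is the fraction of molecules in a stable, slowly
exchanging chromatin-bound pool, $k_{off,1} \ge k_{off,2}$ (per minute) are
the off-rates of the dynamic and stable pools, and $P$ is the asymptotic
redistribution level (1 for a fully normalised signal). The residence time
of one binding event is $\tau = 1/k_{off}$. In inverse FRAP the measured
unbleached-minus-bleached difference signal is the complement,
$P - a(t)$, decaying from $P$ to 0; both conventions share the same
parameters and `fit_exponential()` exposes them through its `direction`
argument. A single-population model is the special case $d_S = 1$ with one
rate.

**Normalisation.** Raw traces carry ROI, whole-nucleus, and background
intensities. We use the background-subtracted double ratio scaled to the
pre-bleach mean,

$$N(t) = \frac{(\mathrm{roi}-\mathrm{bg})/(\mathrm{nuc}-\mathrm{bg})}
{\left\langle(\mathrm{roi}-\mathrm{bg})/(\mathrm{nuc}-\mathrm{bg})
\right\rangle_{\mathrm{pre}}},$$

so that any acquisition photobleaching affecting ROI and nucleus by a
common multiplicative factor cancels exactly, and the pre-bleach mean is 1
by construction. The literature contains several variants of this
correction; we fixed the double-ratio form because it is the standard
acquisition-bleaching correction and makes the cancellation property
testable (the test suite asserts it at machine precision).

**Fitting.** Bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) on the post-bleach frames, times converted to
minutes: $d_S \in [0,1]$, rates in $[10^{-7}, 600]$ per minute, $P \in
(0, 2]$. The lower rate bound keeps pools far more stable than the
acquisition window from underflowing the solver; the upper bound
($\tau = 0.1$ s) admits a sub-frame diffusive component — spot-FRAP
recoveries contain an immediate jump from freely diffusing molecules, and
a ceiling near the frame rate would force that jump into the slow pool and
bias the bound fraction downward — while still excluding degenerate
infinite rates. The optimiser is started from several points, one of which
is the single-exponential solution, so the two-population fit can never
end with a worse residual sum of squares than the nested one-population
fit. Fits are unweighted (homoscedastic noise; see the generator below).
Constant traces (no bleach contrast) return a flagged non-converged
result rather than an error. For spot-FRAP data the first post-bleach
frame may be dropped (`drop_first`): at the bleach instant the diffusive
pool has already re-equilibrated, which a finite-rate model cannot
represent at $t = 0$.

**Model selection.** The study reports *when* one population suffices but
not the criterion; we use the extra sum of squares F-test of the nested
models, $F = \frac{(RSS_1 - RSS_2)/2}{RSS_2/(n-4)}$, choosing the
two-population model only at $p < 0.05$. Ties and non-converged
two-population fits fall back to the one-population model. Note that the
expected false-selection rate under a true one-population model is the
test's $\alpha$, so about 5% of one-population cells are expected to be
(wrongly) called two-population — this is a property of any
significance-based selection rule, not a defect.

**Stable-pool residence time.** Movies are far shorter than the stable
pool's residence time (hours), so $k_{off,2}$ is identified mostly by the
late-time slope and carries wide uncertainty; the stable *fraction* $d_S$
is the headline estimate, and the stable residence time should be read as
"at least hours". This mirrors how such experiments are usually
interpreted.

**Group summaries.** Per-cell estimates are summarised as mean ± s.e.m.
with an unpaired Welch t-test (default) or Mann–Whitney U test between
conditions.

## 2. The photobleaching generator

`simulate_ifrap()` and `simulate_frap()` are exact forward models of the
curves above, producing raw ROI/nucleus/background tables:

* iFRAP difference convention: post-bleach ROI carries
  $b\left[(1-d_S)e^{-k_1 t} + d_S e^{-k_2 t}\right]$ of the pre-bleach
  amplitude, $b$ the bleach depth (1 at full laser power, the default).
* spot FRAP: $F(t) = (1-b) + b\,[d + (1-d)R(t)]$ with $d$ the diffusive
  fraction recovering within one frame and $R(t)$ the bound-pool recovery.
  The diffusive pool is modelled as instantaneous because the frame
  interval (1 s) is much longer than diffusion across a 2 µm spot.
* acquisition photobleaching multiplies ROI and nucleus by $e^{-\beta t}$
  (cancelled by normalisation — asserted to $10^{-9}$ in tests);
* Gaussian homoscedastic noise with sd `noise_sd` × baseline (default
  0.02), the simplest model consistent with high-count fluorescence;
  every trace is deterministic given its seed.

Presets encode the study conditions: G2 cohesin (40% stable pool,
$\tau$ 17.5 min / 10.5 h, 30 s frames over ~2 h), G1 cohesin (single pool,
20 min), and sororin (75% bound pool, $\tau$ 100 s in S phase / 70 s in
G2, 25% diffusive pool, 240 × 1 s frames, 10 pre-bleach frames). The
inverse-FRAP frame interval (30 s) is our choice — the acquisition must
span several dynamic-pool residence times for $\tau \approx 17.5$ min to
be identifiable; the movie length then matches the ~2 h recoveries the
imaging experiments describe.

What the generator does *not* emulate: cell-to-cell parameter
variability, intensity-dependent (shot) noise, spatial bleach profiles,
reversible photophysics, and focus drift. Passing round-trip tests
therefore demonstrates estimator correctness under the model's own
assumptions, not robustness to every artefact of real microscopy.

## 3. Binned enrichment calling (two-state Poisson HMM)

Read tracks are binned at 1,000 bp. Enrichment is called per chromosome
with a two-state (background/enriched) hidden Markov model with Poisson
emissions, $c_b \sim \mathrm{Pois}(\lambda_{s}\, e_b)$, where the per-bin
exposure $e_b = (\tilde c_b + 1)/(\overline{c} + 1)$ is derived from a
matched control track smoothed over 25 bins, $\tilde c_b$. Smoothing
matters: the control's job is to capture broad coverage biases
(mappability, copy number), and at low control depth the raw per-bin
ratio is dominated by Poisson noise — an unlucky zero deflates the local
exposure several-fold and falsely flags ordinary treatment counts.
Parameters are fit by Baum–Welch EM: rates initialised at the 50th and
99th percentiles of the non-zero counts, self-transitions at 0.99, and
the initial state distribution started at the stationary distribution of
the starting transition matrix and then re-estimated as a free EM
parameter — re-tying it to the transition matrix each iteration would
break the monotone-likelihood guarantee that the tests assert. EM stops
when the log-likelihood improves by less than `em_tol` (default 1e-6) or
after `max_em_iters` (default 100). States are relabeled after fitting so
$\lambda_{enr} > \lambda_{bg}$; fits with rates within 2% of each other
are flagged degenerate and yield no peaks (a constant track has no
distinguishable enriched state). Posterior state probabilities come from
scaled forward–backward smoothing; bins with posterior strictly greater
than 0.5 are kept and adjacent kept bins are merged into peaks.

The Poisson emission model is a simplification of negative-binomial
callers; it is exact for the generator below and adequate for planted
truth recovery, but real ChIP-seq overdispersion would widen the
background tail — an extension point, not a current feature.

## 4. The replication-timing genome generator

A small genome (default 3 × 10 Mbp) is partitioned into replication-timing
domains with exponential lengths (mean 1 Mbp, rounded to bins); each
domain replicates instantaneously at a time drawn uniformly in an 8 h
S phase. This matches the abstraction of pulse-labelling experiments,
which only resolve whether a region replicated inside the pulse window.
Within that genome:

* a BrdU-pulse DIP track gives bins replicated inside the pulse
  (default 0–2 h) Poisson mean `depth × fold` (defaults 5 × 8), all
  others `depth`; the control is flat;
* 2,000 cohesin sites of 500 bp are placed uniformly, non-overlapping,
  and — deliberately — identically across simulated cell-cycle stages, so
  any co-occupancy signal is attributable to the replication constraint
  rather than site movement;
* sororin sites are the cohesin sites whose DNA has replicated by the
  sampling time (end of the early pulse for "early S"; end of S phase for
  "G2"), each retained with probability 0.8 (ChIP efficiency; our choice,
  in the range needed for several hundred early-S sites at this scale);
* ChIP tracks are generated from sites with the same Poisson machinery.

The default scale keeps the full pipeline under a minute per seed on one
CPU while leaving hundreds of peaks per condition; the methods are
scale-free, and all sizes are configurable.

## 5. Co-occupancy statistics

**Placement p-value.** For a query interval of width $w$ on a chromosome
of length $L$, with observed closeness $D$ to the reference set, the
p-value is the fraction of the $L-w+1$ possible placements that are at
least as close:

$$p = \frac{\#\{s \in [0, L-w] : D([s,s+w), \mathrm{refs}) \le D_{obs}\}}
{L-w+1}.$$

The closeness metric is 0 for an overlap of ≥ 1 bp and gap + 1 otherwise
(book-ended intervals count as distance 1, the convention genomic
closest-feature tools use); the per-query `distance` reported alongside
is the plain gap. With this metric, a query overlapping a reference
counts only overlapping placements as favourable — book-ended placements
are strictly farther — which makes the analytic computation agree exactly
with exhaustive enumeration (asserted on 1,000 random instances). The
analytic form unions the per-reference favourable windows
$[a - w + 1 - D,\; b - 1 + D]$ before counting, so overlapping windows
are not double-counted. The placement domain is the query's whole
chromosome, matching the randomised control below. $p$ is always in
$(0,1]$: the observed placement is itself favourable.

One consequence worth knowing: the smallest achievable p-value is roughly
the reference set's coverage of the chromosome. Against references that
are Mbp-scale replicated *domains*, even a query dead-centre inside a
domain has $p \approx$ coverage (~0.25 at the defaults), so the fraction
of queries below 0.05 can be structurally zero for observed and null
alike. The p-value *distribution* (ECDF), compared to its shuffle null,
is therefore the primary output, and the end-to-end comparison uses a
one-sided Kolmogorov–Smirnov test of observed vs null p-values.

**Shuffle null.** Each query keeps its chromosome and width and receives
a uniform start in $[0, L-w]$; shuffled intervals may overlap each other
and the references (the default behaviour of genomic shuffling tools).
100 rounds by default; pooled shuffled p-values form the null sample.
Queries on chromosomes with no reference are excluded and counted.

**Common-site bookkeeping.** `overlap_stats()` counts records of each set
overlapping (≥ 1 bp) the other and the percentages unique to each — the
arithmetic behind statements like "49.6% of early-S peaks are absent from
the G2 set".

## 6. Pipeline, seeds, and numerical choices

`run_pipeline()` chains simulate → call → co-occupancy → bookkeeping and
writes every intermediate file in standard formats (chromosome sizes,
bedGraph, BED) plus a JSON report; re-running a configuration reproduces
the report exactly. A single master seed fans out to per-stage seeds via
a fixed polynomial hash of the stage name (`derive_seed()`), all within
31 bits, so stages never share a stream and adding a stage never shifts
another's randomness. The numbered scripts under `analysis/` run the same
stages file-by-file.

Coordinates are 0-based half-open in all files (BED convention) and
1-based closed inside R (`GenomicRanges`); conversion happens only at
I/O. Strand is ignored throughout. Intervals may overlap within a set;
overlap means ≥ 1 shared bp. Ties in model selection fall to the simpler
model; ties in nearest-reference distance are harmless (the distance, not
the identity, enters the statistic).

Problem sizes used by the test and acceptance runs — cohorts of 10–15
cells, 100-seed selection panels, the 30 Mbp genome with 100 shuffle
rounds, 1,000-instance p-value oracle sweeps — were chosen so the whole
suite exercises every claim in minutes on a single CPU while keeping
every statistical margin wide (e.g. planted-peak recovery is asserted at
recall ≥ 0.90 where the measured value is ~1.0).

## 7. Known limitations

* The exchange model ignores binding-site heterogeneity beyond two pools
  and reaction–diffusion coupling; FRAP recoveries limited by diffusion
  would need an explicit spatial model.
* Poisson emissions understate real sequencing overdispersion.
* The placement p-value conditions on the reference set and the query's
  chromosome and width only; it does not model query–query dependence
  (peaks of one set are not independent draws).
* Replication is instantaneous per domain; fork progression within
  domains, origin structure, and cell-to-cell replication-timing
  variability are not modelled.
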