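# cohesindyn

Quantitative analysis of cohesin and sororin chromatin dynamics, for
researchers studying sister chromatid cohesion: how stably does cohesin
bind chromatin through the cell cycle, and where does its stabilizer
sororin sit relative to replicated DNA?

The package implements two analysis arms and the synthetic generators
needed to exercise them end to end:

1. **Photobleaching kinetics** (iFRAP/FRAP). Normalised fluorescence
   traces are fit with a two-population chromatin-exchange model
   `a(t) = P[(1-dS)(1-e^(-kOff1·t)) + dS(1-e^(-kOff2·t))]`, yielding the
   stable-pool fraction `dS` and residence times `τ = 1/kOff`. One- vs
   two-population models are chosen by a nested extra-sum-of-squares
   F-test; conditions are compared by Welch t-test or Mann–Whitney U.
2. **Replication-coupled co-occupancy.** Binned read tracks (ChIP-seq of
   cohesin/sororin, BrdU-pulse DIP-seq of replicated DNA) are segmented by
   a two-state Poisson HMM (Baum–Welch EM, forward–backward posteriors,
   posterior > 0.5, adjacent bins merged). Co-occupancy of a query peak
   set with a reference set is scored per query by the analytic
   closest-interval placement p-value
   `p = #{placements at least as close}/(L − w + 1)` and compared to a
   100-round shuffle null; common-site bookkeeping reports the fraction
   of peaks unique to each condition.

Synthetic generators provide photobleaching cohorts with known kinetics
and a genome with replication-timing domains, cohesin sites, and
sororin sites restricted to already-replicated DNA — so the headline
biology (sororin tracks replicated DNA in early S phase; the association
with early-replicating DNA dissolves by G2) is reproducible from a single
seed.

## Worked example

Simulate a G2 cohesin inverse-FRAP cohort, fit it, and summarise:

```r
library(cohesindyn)

cfg   <- preset_sim_config("g2-smc3", seed = 1)   # 40% stable pool truth
cells <- simulate_cells(cfg, 10, mode = "ifrap")
fits  <- lapply(cells, function(tr)
  fit_exponential(normalize_trace(tr), "bi", "decay"))
summarize_group(fits, "dS")$mean                   # 0.3961
summarize_group(fits, "residence_time_fast")$mean  # 17.56 (minutes)
```

The full genomics arm in one call:

```r
rep1 <- run_pipeline(pipeline_config(seed = 1))
rep1$cooccupancy_early$ks_stat   # 0.527  (early-S sororin vs replicated DNA)
rep1$cooccupancy_early$ks_p      # 0 (below double precision)
rep1$cooccupancy_g2$ks_stat      # 0.009  (same test for the G2 peak set)
```

The KS statistic compares the observed placement p-value ECDF with its
shuffle null: early-S sororin peaks sit far closer to early-replicated
regions than random placement (large KS, vanishing p), while by G2 the
association has largely dissolved (small KS) — with cohesin site
positions held identical across stages by construction.

The same stages are available as numbered drivers writing standard-format
files and tables under `results/`:

```sh
Rscript analysis/01_simulate_photobleach.R   # trace cohorts + manifest
Rscript analysis/02_fit_kinetics.R           # per-cell fits, group summary
Rscript analysis/03_simulate_genome.R        # sizes/bedGraph/BED ground truth
Rscript analysis/04_call_peaks.R             # HMM peak calls + model JSON
Rscript analysis/05_cooccupancy.R            # p-value ECDFs, bookkeeping
```

Stage 2 prints, for example:

```
g1-smc3   : 0/10 cells two-population; single pool, tau 19.92 +/- 0.07 min
g2-smc3   : 10/10 cells two-population; stable fraction 39.7% +/- 0.5, tau_fast 17.36 min
sororin residence time S vs G2: 102.2 s vs 69.4 s; t = 22.63, p = 5.9e-11
```

i.e. the G1 cohort is a single ~20 min dynamic pool, the G2 cohort splits
into ~60% dynamic / ~40% stable, and sororin exchanges within minutes —
the stabilizer turns over rapidly on the complexes it stabilizes.

## Layout

- `R/` — package code: kinetics model and fitting, trace normalisation,
  genome/interval/track containers and I/O, Poisson HMM, co-occupancy
  statistics, generators, pipeline.
- `analysis/` — numbered narrative drivers over the package.
- `tests/testthat/` — unit, property, and end-to-end suites with
  independent oracles (exhaustive HMM enumeration, brute-force placement
  counting, closed-form arithmetic).
- `vignettes/cohesin-dynamics-methods.Rmd` — models, assumptions,
  numerical choices, and limitations.
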