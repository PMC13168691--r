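# telosim

Simulation and inference tools for replicative senescence driven by the
**shortest telomere** in telomerase-negative budding yeast, and for the
genome instability that arises next to it.

## Who this is for

Researchers analysing single-cell microfluidics lineages of senescing
yeast, single-molecule telomere sequencing, or fluctuation assays — and
anyone who wants a fully synthetic, seeded test bed for those analyses
without downloading raw data.

## What it implements

**Telomere dynamics and senescence.**  A cell carries 32 telomeres
(natively Gaussian, 300 ± 75 bp).  Each division, every telomere
independently shortens with probability 1/2 by one G-overhang length
(uniform 6–11 nt) — the DNA end-replication problem, E[loss] = 4.25 bp
per division.  An inducible endonuclease can truncate one telomere to a
defined length ℓ_cut during a galactose window, with a calibrated
per-division cut probability.  Senescence follows a Type A / Type B state
machine driven by the shortest telomere length ℓ:

* p_sen,A(ℓ) = 1 / (1 + exp((ℓ − 36)/1)) — a near-deterministic threshold
  at ℓ_min,A = 36 bp for abrupt (Type A) onset;
* p_nta(ℓ) = min(1, 0.33·e^(−ℓ/40)) — conversion to the Type B route of
  reversible prolonged-cycle episodes;
* p_sen,B = 0.03 per division — length-independent Type B onset.

Onset starts 2–4 terminal prolonged cycles, then death.  Cycle durations
are per-medium calibrated mixtures (raffinose mean 145 min, long-cycle
threshold 290 min; galactose 140/224 min).

**Fitting.**  Cut-probability calibration by closed-form inversion;
threshold-length scans against observed onset medians; ordered-lifespan
envelope comparison (rank-wise mean and central-95% band over simulated
cohorts).

**Single-molecule sequence analysis.**  TG₁₋₃ repeat generation and
validation, telomerase-extension simulation on the 3'-ACACACACCCACACCAC-5'
template, divergence-point calling, end-position histograms, and
shortening-step/rate inference.

**Fluctuation analysis.**  An exact forward Luria–Delbrück simulator,
p0 and Ma–Sandri–Sarkar maximum-likelihood rate estimators with 95%
profile-likelihood CIs, partial-plating correction, fold changes, and
dual-marker (Can^R / 5-FOA / ura) event classification separating gross
chromosomal rearrangements from point mutations.

## Worked example

```r
library(telosim)

# a cohort of 500 lineages whose construct telomere is cut to 50 bp
co <- simulate_cohort(500, "FC50", seed = 1)
co$summary$median_onset          # 4        divisions from galactose to onset
co$summary$frac_cut              # 0.954    lineages cut within the window

# telomerase-negative control without the construct
nofc <- simulate_cohort(500, "noFC", seed = 2)
nofc$summary$median_lifespan     # 27       generations to death
round(nofc$summary$frac_type_B, 2)  # 0.49  lineages with reversible arrests

# scan the senescence threshold against observed onset medians
fit <- threshold_scan(c(FC40 = 2.5, FC50 = 4, FC70 = 9),
                      candidates = seq(20, 60, 2),
                      n_sims_per_candidate = 200, seed = 3)
fit$best_threshold               # 38       bp (33-39 across seeds)

# fluctuation assay: mutation rate with 95% CI
ex <- simulate_luria_delbruck(rate = 2e-8, n0 = 1000, nt = 1000 * 2^17,
                              n_cultures = 20, seed = 4)
estimate_rate_mle(ex)            # rate 1.95e-08 [95% CI 1.24e-08 - 2.85e-08]
```

The onset medians (≈ 2.5, 4 and 9 divisions for cuts to 40, 50 and 70 bp),
the ~30-generation control lifespan, the 40–60% Type B fraction, the
≥ 80% cut efficiency at 9 h, the ~52% of cut molecules still unshortened
at ~1.5 population doublings, and the ~4.3 bp/PD population shortening
rate are the quantitative anchors the model is calibrated against; the
test suite (`tests/testthat/test-acceptance.R`) checks each at its stated
tolerance.

## Command line

```sh
Rscript -e 'telosim::telosim_cli()' simulate-lineages --condition FC50 \
    --n 200 --seed 1 --out lineages.tsv
Rscript -e 'telosim::telosim_cli()' generate-control --n 100 --out ctl.tsv
Rscript -e 'telosim::telosim_cli()' fluctuation --counts plate.tsv --method mle
```

See `vignettes/telosim-methods.Rmd` for the model's assumptions,
calibration derivations, numerical choices and limitations.
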