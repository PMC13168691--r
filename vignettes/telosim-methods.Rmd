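---
title: "Modelling replicative senescence from the shortest telomere: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling replicative senescence from the shortest telomere: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telosim)
```

# The biological system and the model

In telomerase-negative budding yeast, telomeres shorten at every division
because of the DNA end-replication problem, and cells enter replicative
senescence — a checkpoint-enforced permanent arrest — once telomeres become
critically short.  `telosim` implements a stochastic single-lineage model
of this process, built around three coupled components:

1. **Telomere dynamics.**  A cell carries 32 telomeres with lengths in bp
   (natively Gaussian, 300 ± 75 bp, truncated at 1 bp; lineage
   simulations additionally apply a 100 bp homeostatic floor to the
   initial state, because cells enter the experiment from
   telomerase-positive growth and telomerase preferentially elongates
   short telomeres, so the steady state carries essentially no telomere
   in the critically short range).  At each division
   every telomere independently shortens with probability 1/2 (one sister
   out of two inherits the loss) by one G-overhang length, drawn uniformly
   from 6–11 nt.  The expected population rate is therefore
   0.5 × 8.5 = 4.25 bp per division, inside the 3–5 bp/division band
   measured on telomere populations.  Lengths never increase (there is no
   telomerase) and are floored at 0.
2. **An inducible cut.**  One telomere can carry a construct that a
   galactose-induced endonuclease truncates to a defined residual length
   $\ell_{cut}$.  The cut acts at divisions: while the division time lies
   in the window $[t_{gal}, t_{raf} + delay]$ (galactose at 6 h for 6 h,
   enzyme persistence $delay = 9$ h), an uncut lineage is cut with a
   per-division probability $q_{cut}$.  $q_{cut}$ is calibrated by
   inverting $1-(1-q)^k$ so that the cumulative cut fraction matches the
   measured cutting efficiency (85% at 7.5 h after galactose, the midpoint
   of the reported 80–90% within 6–9 h); with the default cycle clocks
   this gives $q_{cut} \approx 0.43$ and ≈ 88–90% of lineages cut by 9 h.
3. **A Type A / Type B senescence state machine.**  Transition
   probabilities are evaluated each division on the length $\ell$ of the
   *shortest* telomere:
   - $p_{sen,A}(\ell) = 1/(1+\exp((\ell - \ell_{min,A})/w))$, a logistic
     step centred at $\ell_{min,A} = 36$ bp with width $w = 1$ bp — a
     near-deterministic threshold;
   - $p_{nta}(\ell) = \min(1, a\,e^{-\ell/b})$, the probability of a first
     reversible ("non-terminal") prolonged-cycle episode, which converts
     the lineage to the Type B route (episodes have geometric length,
     mean 2, and recur under the same law);
   - $p_{sen,B}$, a constant per-division onset probability for Type B
     lineages; because the threshold scan applies to both routes, Type B
     cells additionally remain subject to $p_{sen,A}(\ell)$.

   Senescence onset starts a terminal block of 2–4 consecutive extremely
   prolonged cycles followed by death.  A telomere-independent accidental
   death probability of 0.5% per division applies to cycling cells (the
   terminal block always runs to completion, keeping the 2–4-cycle
   invariant exact).

# Cell-cycle durations: a mixture calibrated by moment matching

The control statistics to reproduce are: mean cycle duration ≈ 145 min in
raffinose and ≈ 140 min in galactose; a prolonged-cycle threshold defined
as dataset mean + 2 SD equal to 290 and 224 min respectively; and 4.3%
(raffinose) / 4.2% (galactose) of cycles above that threshold.  These are
mutually inconsistent with a single Gaussian: a Gaussian places only 2.3%
of its mass above its own mean + 2 SD.  `telosim` therefore models control
durations as a two-component mixture — normal cycles (Gaussian truncated
below the threshold) plus rare spontaneous long cycles
(threshold + Exponential) at the printed baseline rate — and
`calibrate_cycle_medium()` solves the normal component's location and
spread by moment matching so that the mixture's mean, SD, and hence the
mean + 2 SD threshold reproduce the printed values exactly.  The derived
spreads (72.5 and 42 min at the dataset level) are not printed anywhere;
they follow from the threshold definition.

In the senescence simulation, normal cycles come from the normal
component and arrest cycles (episodes and terminal blocks) from the
long-cycle law, so duration-threshold classification of simulated records
is exact by construction; the spontaneous baseline long cycles appear
only in the telomerase-positive control generator, where they are part of
the printed 4.3%/4.2% statistic.

# Timing conventions

*Generation counting.*  Time 0 is telomerase inactivation; the generation
counter resets at galactose addition, the first cell born under galactose
having generation 0.  Senescence onset is the generation index of the
first terminal prolonged cycle; onset medians are computed over lineages
that actually senesce within the 120 h recording horizon, and lineages
arrested before galactose are excluded, mirroring the experimental
analysis.

*The cut division.*  In the lineage model the division at which the cut
fires leaves the construct telomere at exactly $\ell_{cut}$ — the cut
defines the length — and end-replication shortening of the cut end starts
at the next division.  In the bulk *molecule* simulation used for the
sequencing time course (`simulate_bulk_cut_population()`), the freshly
cut end does join the cut division's shortening coin, scaled by
`p_pre_replication = 0.75`: the cleavage must precede the replication
fork's passage over the telomere for that division's overhang loss to
apply, and yeast telomeres replicate in late S phase.  The molecule-level
convention is forced by the measured position distribution (≈ 52% of cut
molecules still unshortened at ~1.5 population doublings, halving every
subsequent doubling); the cell-level convention follows the model
definition of the cut.  Both conventions are explicit parameters.

*Discrete medians.*  Onset generations are small integers, so their
sample median is quantized to steps of 0.5.  For fitting, `telosim` uses
the mid-distribution (interpolated) median — integer values treated as
unit bins with the empirical CDF interpolated linearly — which is a
smooth location statistic for the same quantity.  The plain median is
reported alongside it in cohort summaries.

# Calibration of the free transition-law parameters

The functional forms above have three parameters that the source
literature does not print: `nta_scale`, `nta_decay` and `p_sen_B_const`.
They were calibrated once against the two printed population anchors for
telomerase-negative no-construct cohorts — a Type B fraction between 40
and 60% and a median lifespan of ~30 generations — giving
`nta_scale = 0.33`, `nta_decay = 40` bp and `p_sen_B_const = 0.03` per
division.  With these defaults the simulated noFC cohort has a Type B
fraction of ~0.5 and a median lifespan of ~27 generations (inside the
stated ± 8 tolerance but on the low side: the running minimum of 32
shortening telomeres erodes slightly faster than a single telomere, and
the model does not include the slow-growth adaptation real senescent
lineages show).  The cut-cohort onset medians at threshold 36 bp are
≈ 2.5 (FC40), ≈ 4.4 (FC50) and ≈ 8.6 (FC70) divisions, and scanning the
threshold against the reported medians (2.5, 4, 9) recovers 34–36 bp.

# The threshold scan

`threshold_scan()` simulates cohorts per candidate threshold and scores
the summed squared error of interpolated median onsets against observed
medians, breaking ties toward the smaller candidate.  The loss surface is
smooth but shallow near its minimum (± 2–3 bp at 200 lineages per
candidate and condition); parameter-recovery tests on self-generated
cohorts require the best candidate within ± 3 bp of the generating truth
in ≥ 90% of repetitions.  `envelope_compare()` provides the complementary
distribution-level check: rank-wise mean and central-95% band of ordered
senescing-lineage lifespans over repeated simulated cohorts, with the
fraction of observed order statistics inside the band as the agreement
summary.

# Single-molecule sequence analysis

Synthetic telomeric repeats follow a TG$_{1-3}$ grammar — alternating
G-runs of 1–3 nt and T-runs of 1–2 nt, uniform within runs (the exact run
distribution is a design choice; the generator and the grammar validator
are duals, and the long-run G fraction is 2/3.5 ≈ 0.571 by run-length
arithmetic).  Telomerase extension anneals the substrate's 3' suffix on
the template RNA (3'-ACACACACCCACACCAC-5'), choosing uniformly among the
longest complementary registers, and appends the complement of a random
number of template bases; iterated rounds produce the divergent
degenerate tails seen in real re-elongated telomeres (a substrate ending
…GGG annealed at the CCC yields 5'-TGTG…-3', the reported most common
extension).

Divergence-point calling scans anchor-aligned columns left to right; a
column disagrees when its minority count is at least the tolerance
fraction (default 5%) *and* at least 2 reads (1 when fewer than 4 reads
cover the column), and a call requires 3 consecutive disagreeing columns.
The two-out-of-n rule prevents a single sequencing error in a deep column
from breaching a 5% fraction threshold, and the run requirement suppresses
isolated noisy columns; the reported position is the length of the shared
prefix.  On noise-free constructed groups the call equals the true
longest common prefix exactly, and it is stable under 1% substitution
noise.  The synthetic read model applies i.i.d. substitutions only —
indels of real long-read chemistry are out of scope (the consensus stage
of the real pipeline absorbed them), which means a green divergence test
does not establish indel robustness.

The construct coordinate map places the blunt cut end of the 50-bp
construct at position 57 (50 proximal repeat nt + 7 retained target nt)
and the staggered fill-in product at 58, each with default probability
1/2.  The target-sequence stand-in and the subtelomere anchor are
synthetic sequences (`SYNTH_TTDNA`, `SYNTH_ANCHOR`); real-data users must
supply their own construct map.

# Fluctuation analysis

`simulate_luria_delbruck()` is a forward generative process, independent
of the estimators: per doubling generation the number of new mutations is
binomial over the dividing cells; each mutation is assigned its founding
division's time within the doubling interval (arrival density
proportional to the growing population), and its clone expands
exponentially to sampling, contributing
$\lfloor 2^{G-g+1}/(1+U)\rfloor$ cells with $U\sim\mathrm{Unif}(0,1)$.
This reproduces the classic Luria–Delbrück clone-size law
$P(k) = 1/(k(k+1))$ exactly without ever sampling the asymptotic count
distribution.  (A first implementation doubled clones synchronously,
which concentrates clone sizes on powers of two and visibly mis-calibrates
the MSS likelihood — CI coverage dropped to ~87%.)

`estimate_rate_mle()` maximizes the Ma–Sandri–Sarkar likelihood; counts
above a cap (default 128) are treated as right-censored through the tail
probability, keeping the $O(k^2)$ recursion bounded while retaining
jackpot information.  Partial plating enters as binomial thinning of the
count distribution inside the likelihood, so the estimate is the
whole-culture $m$ and the rate is $m/N_t$ regardless of plating
efficiency.  The 95% CI is the $\chi^2_1$ profile-likelihood interval;
measured coverage on simulated experiments (20 cultures, $m = 2$) is
94–95%.  `estimate_rate_p0()` is the closed-form companion
($-\ln p_0/N_t$ with a Wilson interval on $p_0$); the exact CI
construction of the original analysis code is not printed anywhere, so
the profile-likelihood choice is a declared substitution.  Fold changes
propagate CI half-widths on the log scale assuming independence.

# What the synthetic data do and do not establish

The generators emulate: microfluidics lineage tables (per-cycle durations,
media, arrest flags, fates), single-telomere read libraries with known
end positions and optional telomerase tails, and fluctuation plate-count
tables — each with a ground-truth sidecar, as pure functions of
(parameters, seed).  They do not emulate: survivor-precursor lineages
(the long-lived tail reported for the 70-bp cohort), sister-telomere
coupling or leading/lagging asymmetry (telomeres shorten independently;
the coupling question is exposed as a configuration point through the
overhang model), raw long-read signal or indels, image data, or
post-senescence escape.  Green tests therefore establish internal
consistency of the method chain on this stated world, and agreement with
the printed population statistics — not correctness on raw experimental
exports.

# Known limitations

* For a 70-bp cut, the cut telomere is the cell's shortest in ~97% of
  post-cut cell divisions, not ≥ 99%: the minimum of the 31 native
  telomeres (initially ~147 ± 25 bp) erodes into the cut telomere's
  range near onset.  No Gaussian(300, 75) initial state avoids this;
  the corresponding acceptance check is deliberately left failing for
  that cut length and analysed in the project notes.
* The noFC median lifespan sits at ~27 generations against the reported
  ~30 (within tolerance); matching it exactly would require slowing the
  effective shortening of the running minimum, for which there is no
  printed calibration target.
* The per-division cut probability is calibrated from a two-point summary
  (80–90% within 6–9 h) rather than the full cut-kinetics curve.
* `p_sen_B` is length-independent by design; any true length dependence
  of the Type B onset is absorbed into the threshold component.
* The MSS likelihood assumes equal $N_t$ across cultures (the mean is
  used); strongly unequal culture sizes would need a per-culture
  likelihood.
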