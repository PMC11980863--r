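---
title: "Molecular-clock tip dating of heterochronous mitogenomes: models and methods"
author: "tipdater"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-clock tip dating: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipdater)
```

# The problem

Radiocarbon dating fails beyond roughly 50 thousand years (ka), yet ancient-DNA
work increasingly reaches specimens hundreds of thousands to over a million
years old. For such deep-time samples the sequence itself carries the only
usable age signal: under a molecular clock, a sample's age determines how many
substitutions separate it from securely dated relatives. Bayesian *tip dating*
formalises this: tips with finite radiocarbon ages are fixed in time and
calibrate the clock, undated tips receive an age prior, and MCMC integrates
over trees, rates and model parameters to yield a posterior age for each
undated sample.

`tipdater` implements this pipeline end to end for mitogenome-scale data:
consensus calling from read pileups, alignment post-processing, a partitioned
likelihood on dated trees, coalescent tree priors, Metropolis–Hastings
sampling, the diagnostics a practitioner needs (ESS, chain-pair convergence,
unimodality), and the study protocols built on top (single-sample dating,
multi-sample dating, bias experiments, held-out validation, joint
maximum-clade-credibility phylogenies). A coalescent simulator generates
synthetic datasets with known truth so every layer can be tested by parameter
recovery rather than by authority.

# The model

## Sequence likelihood

The alignment is split six ways — tRNA, rRNA, first/second/third codon
positions, control region — and each partition is modelled as HKY with a
discrete-Gamma ("+G", 4 equal-weight categories, rates equal to the
within-bin means of a Gamma(α, α)) and an invariant-site class ("+I",
proportion `p_inv`). The tRNA partition drops the Gamma, i.e. HKY+I. The HKY
generator is normalised to one expected substitution per site per unit
distance at stationarity, and the G+I mixture is renormalised to mean rate 1,
so the strict-clock rate keeps interpretable units (substitutions/site/year)
no matter the values of α and `p_inv`. A branch from a parent of age $t_p$ to
a child of age $t_c$ (ages in years before present) has expected
substitutions

$$ d = \mu \cdot r_k \cdot c_j \cdot (t_p - t_c), $$

with $\mu$ the shared strict-clock rate, $r_k$ the partition's relative rate
(constrained to column-count-weighted mean 1 across partitions) and $c_j$ the
site's rate category. Likelihoods are computed by Felsenstein pruning in C++
with per-node rescaling and site-pattern compression; `N` and `-` are fully
ambiguous states. Base frequencies are fixed at their empirical per-partition
values — a deliberate dimension reduction at desk scale.

## Tree prior and calibrations

The tree prior is the serially sampled coalescent, either constant-size or a
skygrid-style piecewise-constant trajectory on a user-chosen time grid with a
first-order Gaussian random walk on log sizes (precision τ, Gamma(0.001,
0.001) hyperprior). Effective sizes are parameterised directly in years of
pairwise coalescence time, avoiding an unstated generation time.

Calibrations follow the mammoth-mitogenome study design this package
re-implements: the ingroup/outgroup divergence (the root) carries a
log-normal prior with real-space median 5.3 Ma — the well-constrained
*Loxodonta* versus *Elephas*/*Mammuthus* split — and undated tips carry a
uniform prior, by default 1 ka to 2 Ma. The log-scale standard deviation of
the root calibration is not printed in the source study; the default here is
0.05 (≈ ±10% at 2 s.d.), configurable and echoed in output metadata. Ages
outside a tip's uniform bounds are rejected states (prior −∞), not errors.

Vague parameter priors (all configurable): log-normal(1, 1.25) on κ,
exponential (mean 0.5) on α, uniform(0,1) on `p_inv`, bounded 1/x on the
clock rate and on effective sizes. Relative rates are flat on their
constraint surface.

## Parameter linkage

The study delegated substitution modelling to BEAST and does not state
whether κ, α and `p_inv` were linked across partitions. `run_chain()` links
them (one κ, one α, one `p_inv`, with the tRNA partition dropping the Gamma)
while estimating per-partition relative rates; this halves the free
dimension at desk scale where each partition may hold only a few hundred
columns. The exported prior/posterior evaluators support unlinked sets, so
the choice is a sampler configuration, not a structural limit.

# The sampler

`run_chain()` is a fixed-schedule Metropolis–Hastings sampler:

* log-space scale moves on the clock rate, κ, α, τ and effective sizes;
* a joint **up–down** move multiplying all free node ages and coalescent
  sizes by a factor while dividing the clock rate by it. Without this
  operator the rate–time ridge (only the *product* of rate and duration is
  well constrained) mixes pathologically slowly — in testing the clock-rate
  ESS improved several-fold when it was added;
* uniform-window, scale, prior-independence and **tip-jump** moves on
  undated tip ages. The tip-jump redraws the age from its prior and shifts
  the tip's parent to preserve its height slack, letting a deep tip
  traverse the full prior range in one accepted move rather than by a
  random walk squeezed under its parent;
* uniform node-height slides within parent/child bounds and a root-height
  scale above the older child;
* narrow-exchange topology moves (optional: `topology = "fixed"` keeps the
  starting topology, the mode used by recovery tests, where the simulator's
  true topology is known and only ages are hidden);
* a mass-preserving exchange move on relative rates that keeps the weighted
  mean exactly 1.

Proposal scales are tuned toward ~23% acceptance during burn-in only;
retained samples begin after the burn-in fraction (default 10%, as in the
study). Every stochastic entry point requires an explicit integer seed, and
two runs with the same seed are bit-identical.

Chain length defaults (20,000 proposals, thin 20) are a desk-scale stand-in
for the study's two chains of 100 million BEAST iterations sampled every
10,000. The protocols below keep the study's *structure* — two independent
chains, ESS > 200 thresholds, chain-pair convergence, unimodality — while
the per-run ESS achievable in minutes is naturally far below what week-long
runs deliver; estimates failing the thresholds are returned with honest
flags rather than suppressed.

# Protocols

`single_sample_date()` merges exactly one undated sample with the calibrated
reference tips and outgroups (all other undated samples are excluded by
construction), runs a chain pair, and averages the two chains' posterior
means and 95% HPD endpoints — the study's averaging rule, followed verbatim
even though pooling the traces is statistically tidier. `pool_chains = TRUE`
switches to pooled-trace summaries, the recommended mode whenever desk-scale
chains fall short of the ESS bar: endpoint averaging of two short,
disagreeing chains understates the posterior spread.
`multi_sample_date()` dates several undated tips in one joint MCMC.
`bias_experiment()` reproduces the study's design of sequentially adding the
oldest undated specimens (ordered by true simulated age, the synthetic
analogue of stratigraphic ordering) and contrasting joint with individual
estimates. `validate_known_age()` re-dates held-out calibrated samples as if
undated and reports HPD coverage. `joint_phylogeny()` fixes calibrated tips,
gives formerly undated tips uniform priors over their estimated 95% HPD
ranges, samples topology, and summarises with `mcc_tree()` (maximum
sum-of-log-clade-frequency tree, node heights annotated with matching-clade
means and HPDs).

# The synthetic world

`make_study_dataset()` emulates the study's data: by default ~20 calibrated
tips uniform on 0–50 ka, undated tips with true ages uniform on 50 ka–1.3 Ma,
a present-day outgroup clade whose split age is drawn from the same
log-normal law used as the root calibration, a 16.5 kb six-partition layout
with a masked VNTR inside the control region, and strict-clock HKY+G+I
evolution. Defaults the original study does not state were chosen once for
plausibility and are not revisited: clock rate 2.5e-8 substitutions/site/year
(elephantid mitogenome scale), κ = 25, α = 0.4, `p_inv` = 0.3, relative rates
(tRNA 0.5, rRNA 0.6, codon1 0.7, codon2 0.35, codon3 2.2, control region
2.5, then renormalised), ingroup Ne 250 kyr and outgroup Ne 500 kyr of
pairwise coalescence, negative-binomial pileup depth (the study protocols state no
depth law; chosen to exercise the low-coverage masking rules).

What the generator does *not* emulate: indels and alignment error (sequences
are simulated gap-free; gaps enter only via masking operations),
post-mortem damage, reference bias, and population structure beyond the
ingroup/outgroup split. A green recovery test therefore establishes that the
inference machinery is internally correct and calibrated *for data generated
under its own model class* — not that real mammoth ages are right.

One structural mismatch is intentional and worth naming: the generator
builds the genealogy as ingroup coalescent + outgroup clade joined at a
calibrated split, while the default inference model applies a single
unstructured coalescent to all tips, mirroring the real study (elephant
outgroups inside a mammoth skygrid). At 2 kb that mismatch is not benign: a
single Ne stretched across both the shallow ingroup and the ~5 Ma stem
inflates ingroup node heights (posterior Ne several-fold above truth) and,
through the rate–time ridge, depresses the clock rate by 10–20% — enough to
break nominal coverage of the clock at desk scale. `dating_config()`
therefore offers `structured_root = TRUE`: the coalescent is applied within
the ingroup and within the outgroup clade separately (each with its own
effective size) and the split age is governed by the root calibration
alone. This matches both the generative process and the biology — the
outgroups are distinct genera, not members of one panmictic deme — and in
recovery testing restores Ne and clock-rate calibration. It requires a
fixed topology (the outgroup must stay monophyletic) and a root
calibration. The study-faithful unstructured coalescent remains the
default. Relatedly, desk-scale runs benefit from a flatter κ prior
(`parameter_priors(kappa_sdlog = 4)`, effectively uniform-in-log): the
BEAST-style lognormal(1, 1.25) default measurably shrinks mitochondrial
ts/tv ratios (~25) at 2 kb, under-correcting deep-branch saturation. The
residue after these choices is honest small-data Bayesian shrinkage (α and
`p_inv` remain weakly identified at 2 kb).

# Numerical choices and edge cases

* Consensus thresholds compare exact rationals (cross-multiplication with a
  scaled integer threshold), so a 2/3 agreement correctly fails a 67% rule
  while exactly 67% passes; ties for the majority base cannot pass any
  threshold above 50%, making tie-breaking moot.
* The singleton-column rule removes a column only when exactly one sequence
  has a determinate base and *all* others are gaps; `N` is not a gap
  assignment. All-gap columns are also removed.
* Reference coordinates are 1-based inclusive (GenBank convention);
  annotation transfer walks the reference row's gap pattern. Gap columns
  inside a masked span are masked too — masking is protective.
* The Gamma quantile-bin means use the incomplete-Gamma identity
  `n (F_{α+1}(q_{i+1}) − F_{α+1}(q_i))`, exact up to `pgamma`; the whole
  mixture including the invariant class is rescaled to mean 1.
* HKY transition probabilities use the closed-form eigen-decomposition,
  verified against matrix exponentials to 1e-10; `t = 0` returns the exact
  identity.
* The heterochronous coalescent density integrates the piecewise 1/Ne
  trajectory exactly across epoch boundaries; ties between sampling and
  coalescence times order samplings first.
* ESS uses the initial-positive-sequence (paired autocorrelation)
  truncation; a constant series is an error, not an ESS of N.
* HPD intervals are the shortest contiguous windows over order statistics
  containing ⌈0.95 N⌉ points, ties resolved to the lowest lower endpoint.
* Unimodality is judged by kernel-density mode counting (Silverman
  bandwidth) ignoring local maxima under 10% of the global peak.
* Degenerate inputs: pileups of length 0 give an empty consensus; trees
  require ≥ 2 tips; `p_inv = 1` is rejected; chains fail loudly if no
  finite-posterior initial state is found within 1000 attempts.

# Known limitations

Desk-scale chains rarely reach the study's ESS > 200 bar, so protocol flags
are frequently and honestly `FALSE` in examples; equivalence with BEAST
output is not claimed — correctness is established against brute-force
enumeration, closed forms, independent integrators and prior-sampling
checks instead. Insertions relative to the reference are out of scope for
consensus calling (the pileup is reference-indexed), NEXUS and relaxed
clocks are not implemented, and radiocarbon recalibration is consumed as
input, never computed.
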