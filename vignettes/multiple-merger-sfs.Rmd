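---
title: "Detecting balancing selection under sweepstakes reproduction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting balancing selection under sweepstakes reproduction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-fecundity marine organisms such as Atlantic cod can reproduce by
"sweepstakes": a few individuals contribute enormous, heavy-tailed numbers
of offspring. Genealogies of samples from such populations are not well
described by the Kingman coalescent of binary mergers — several ancestral
lineages can coalesce in a single event. A practical consequence is a
strong excess of singleton variants, which under a Kingman null would be
misread as population growth or pervasive selection. Any claim of
locus-specific selection in such a species therefore needs a
multiple-merger (Λ) coalescent as its neutral null model.

This package implements that inference chain for aligned haploid sequence
data (one consensus allele per individual):

1. classical polymorphism, divergence, differentiation and linkage
   statistics (`summary_stats()`, `divergence()`, `hudson_fst()`,
   `ld_dprime()`);
2. folded and unfolded (outgroup-polarized) site frequency spectra
   (`unfolded_sfs()`, `fold()`, `find_modes()`);
3. expected normalized spectra under Kingman, Beta(2−α, α), point-mass
   (Dirac ψ) and growth-time-changed Kingman models
   (`expected_normalized_sfs()`);
4. minimum-ℓ² grid fitting with likelihood-ratio G tests and approximate
   multinomial log-likelihoods (`fit_model()`, `g_test()`,
   `approx_loglik()`);
5. a synthetic-data generator whose balanced-locus preset emulates a
   122-sequence, 2,500-bp locus split into divergent haplogroups of 43 and
   79 sequences (`simulate_balanced_locus()`, `preset_ckma_like()`).

The genealogical signature of long-standing balancing selection is the
target pattern: two deeply divergent allelic classes behave like isolated
populations, so the unfolded spectrum is trimodal — a singleton mode from
the within-class genealogies plus two high-frequency modes at
complementary classes (the two class sizes), which fold onto a single mode
in the folded spectrum.

## Models

All models are specified through `coal_model(family, param)`.

**Λ-coalescent merger rates.** With `b` active lineages, a given set of
`k` merges at rate
λ<sub>b,k</sub> = ∫ x<sup>k−2</sup>(1−x)<sup>b−k</sup> Λ(dx):

* Kingman: λ<sub>b,2</sub> = 1, no larger mergers;
* Beta(2−α, α): λ<sub>b,k</sub> = B(k−α, b−k+α)/B(2−α, α), with
  1 ≤ α ≤ 2. Smaller α means heavier-tailed offspring numbers (the chance
  of a family of k or more surviving offspring decays like k<sup>−α</sup>);
  α = 2 is degenerate (the Beta(0, 2) measure) and is routed to the exact
  Kingman path;
* Dirac (point mass at ψ): λ<sub>b,k</sub> = ψ<sup>k−2</sup>(1−ψ)<sup>b−k</sup>,
  0 < ψ ≤ 1, where ψ is the fraction of the population replaced by a single
  family in a sweepstakes event.

The total rate of k-mergers is C(b, k)·λ<sub>b,k</sub>. `simulate_genealogy()`
runs the block-counting chain: exponential waiting times at the total
rate, merger size chosen proportionally, blocks chosen uniformly.

**Growth models.** Exponential and algebraic growth are time-changed
Kingman coalescents with backwards relative population size
ν(t) = e<sup>−βt</sup> or ν(t) = (1+t)<sup>−γ</sup>; the pair-coalescence
intensity scales as 1/ν(t). These ν(t) forms are explicit stand-ins: the
growth-model literature the approach derives from parameterizes growth in
more than one way, and no canonical form is fixed by the data layer. Both
reduce exactly to Kingman at β = 0 / γ = 0. Waiting times are obtained by
*analytic* inversion of the cumulative intensity (the integrals invert in
closed form, so no numeric root-finding is used).

**Expected spectra.** The expected normalized spectrum is
φ<sub>i</sub> = E[L<sub>i</sub>]/E[T], where L<sub>i</sub> is the total
length of branches subtending i of n leaves and T the total length. For
Kingman (and the exact-Kingman limits) the closed form
φ<sub>i</sub> ∝ 1/i is used. All other families use Monte Carlo over
genealogies simulated in compiled code, with delta-method standard errors
per class and session-level caching keyed by `(n, family, param, reps,
seed)`. Because a whole fitting grid shares one seed, the ℓ² curve is a
smooth function of the parameter rather than re-randomized per point.

## Fitting and testing

**Minimum ℓ².** For an observed unfolded spectrum ξ with S segregating
sites, ℓ²(model) = Σ<sub>i</sub> (ξ<sub>i</sub>/S − φ<sub>i</sub>)², over
the full class range i = 1..n−1 including zero cells. `fit_model()`
evaluates ℓ² on a parameter grid and reports the arg-min, the curve, and
the Kingman null ℓ²(0). Default grids are α ∈ [1, 2] and ψ ∈ [0.005, 1],
both in steps of 0.005 — fine enough that grid resolution is never the
limiting error; growth grids are β ∈ [0, 20] (step 0.5) and γ ∈ [0, 30]
(step 0.5), spanning visually Kingman-like to extremely singleton-skewed
spectra. Ties break toward the smaller parameter with a recorded tie flag.

**G test.** Expected counts are E<sub>i</sub> = S·φ<sub>i</sub>; adjacent
classes are pooled from the right tail until every pooled expected count
reaches `pool_min`, then G = 2 Σ O ln(O/E) with df = pooled classes − 1 −
fitted parameters. The default `pool_min = 5` follows the classical
goodness-of-fit rule: in simulations at n = 122, S = 90 the E ≥ 1
threshold gives a type-I error near 14% at nominal 5%, while E ≥ 5 gives
about 6%, so the lenient threshold was rejected. Note a caveat on what
"calibrated" means: the G test treats the spectrum as a multinomial draw
given S. Spectra of whole loci are overdispersed relative to multinomial
because all sites share one genealogy, so against full coalescent
replicates the test remains anti-conservative; its calibration is
verified under its own sampling model (multinomial resampling of the
expected spectrum).

**Approximate log-likelihood.** Σ ξ<sub>i</sub> ln φ<sub>i</sub> up to a
constant, with zero Monte-Carlo cells floored at half the smallest
positive φ (the number of floored cells is recorded). Model rankings by
this criterion agree with rankings by ΔG, as both are the multinomial
deviance.

## The synthetic-data generator

`simulate_neutral()` draws one genealogy, then a Poisson((θ/2)·T) number
of mutations placed on branches proportionally to length, each on a fresh
column (infinite sites). The convention E[mutations] = (θ/2)·T makes
E[S] = θ·a₁ under Kingman with a₁ = Σ 1/i, the classical Watterson
relation; it is stated explicitly because simulation conventions differ
across the literature. The outgroup is generated from the ancestral
sequence with Jukes–Cantor substitution chains; the hit rate is chosen so
that the *expected observed* per-site divergence equals the configured
value (i.e. the rate is the Jukes–Cantor correction of the target
divergence). Multiple hits are allowed only on the outgroup lineage.

`simulate_balanced_locus()` joins two independent within-haplogroup
genealogies rather than simulating selection forward in time: the
genealogical argument for balancing selection is precisely that balanced
functional classes accumulate variation like isolated populations, and
this construction reproduces the target spectrum shape with a controllable
truth (every variant column is tagged diagnostic / within-group /
outgroup in `site_map`). Diagnostic columns are fixed-different between
haplogroups, derived alternately in one or the other group relative to the
outgroup, so both complementary high-frequency classes are populated.
Rare recombinants are emulated by giving each sample a small probability
(`swap_rate`) of exchanging one contiguous block of diagnostic columns
for the other haplogroup's alleles — a single-block swap, mirroring the
two-LD-block structure that recombination leaves around a breakpoint.

The preset scenario (`preset_ckma_like()`) fixes n = 122 split 43/79,
L = 2,500, 20 diagnostic sites, within-group Beta coalescent with
α = 1.1 (a strong singleton excess), swap_rate = 0.03, outgroup
divergence 2%, and seed 1732. The within-group mutation rate is not
hand-tuned: it is set from the exact expected total branch length of the
two within-group genealogies (a first-step recursion on the
block-counting chain, `expected_total_length()`) so that the expected
number of segregating sites is 87 (20 diagnostic + 67 within-group).
Since the realized total branch length under α = 1.1 has high variance,
individual datasets scatter widely around that expectation — that is a
property of the model, not a calibration error.

What the generator does *not* emulate: intra-locus recombination within
haplogroups (beyond the diagnostic-block swap), sequencing or consensus
error, base-composition or rate heterogeneity along the sequence, gaps
and missing data in generated output, and any explicit selection
dynamics. A green test on synthetic data therefore establishes the
correctness and internal consistency of the statistics and the fitting
machinery under the stated generative model — not that real data meet
that model.

## Numerical choices and degenerate inputs

* Missing data: columns with a gap or `N` in any retained ingroup
  sequence are excluded from `effective_length`, from S and from
  haplotype calling (complete case); pairwise differences use pairwise
  deletion. Both rules coincide on gap-free data; they are reported so
  users can reconcile published tables computed under other conventions.
* Coordinates are 1-based alignment columns throughout.
* Multi-allelic ingroup sites are dropped from spectra and logged
  (an infinite-sites spectrum has no class for them); sites the outgroup
  cannot polarize (gap, `N`, third allele) are dropped and logged.
* `S = 0` yields a missing Tajima's D (not an error); ℓ² and likelihood
  computations require S > 0 and say so.
* Mode finding uses strict local maxima with plateaus merged to their
  leftmost class and a minimum mode separation (default 2 classes;
  the analysis scripts use 5 for n = 122 spectra) — an explicit, testable
  criterion in place of visual inspection.
* The F_ST estimator is Hudson's 1 − H<sub>w</sub>/H<sub>b</sub> on
  nucleotide differences, with H<sub>w</sub> the group-size-weighted mean
  of per-group mean pairwise differences. Published tables computed with
  other estimators will differ slightly; the permutation test (group
  sizes preserved, P = (#{permuted ≥ observed} + 1)/(n_perm + 1)) is
  estimator-agnostic.
* Tajima's D is reported as the raw statistic; significance should come
  from coalescent simulation under the appropriate null (the machinery in
  this package) rather than the normal/beta approximation.

## Known limitations

* The Dirac family with fixed ψ is *not* uniformly close to Kingman in n:
  the per-event fraction of k ≥ 3 mergers grows like (b−2)ψ/3, so at
  n = 100 even ψ = 0.005 inflates the singleton class by ~0.026 in
  normalized weight. Treating small-ψ Dirac fits as "Kingman-like" is
  safe only when n·ψ is small.
* Growth-model fits on strongly singleton-excess spectra run to the top
  of their grids (the models lack the right tail weight of Λ
  coalescents); the reported fits are then grid-boundary values, flagged
  by inspection of the ℓ² curve.
* No Ξ (simultaneous multiple merger) coalescent, no recombination in
  genealogies, no confidence intervals on fitted parameters (point
  estimates only, matching the grid-search framework).
* Time is in coalescent units throughout; no conversion to generations or
  years is attempted, and the time-scale arguments that motivate
  multiple-merger models (coalescent probability c_N, N^(α−1) scaling)
  are documentation, not computation.
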