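# lambdasfs

Multiple-merger coalescent analysis of site frequency spectra, for
detecting balancing selection in organisms with sweepstakes reproduction.

## The problem

High-fecundity organisms (Atlantic cod is the motivating case) can have
highly skewed, heavy-tailed offspring-number distributions: occasionally a
single family replaces a large fraction of the population. Genealogies
then contain *multiple mergers* — more than two lineages coalescing at
once — and the classical Kingman coalescent is the wrong neutral null.
Against a Kingman null, the resulting singleton excess looks like
population growth or genome-wide selection; against the right
multiple-merger null, genuinely selected loci stand out.

`lambdasfs` provides the full inference chain for aligned haploid
sequences (one consensus allele per individual) with a single outgroup:

* **Summary statistics** — segregating sites *S*, haplotypes *H*,
  haplotype diversity *h*, mean pairwise difference *K*, Watterson's
  θ_S = S/(a₁·L), nucleotide diversity π, Tajima's *D*; Jukes–Cantor
  corrected gross/net divergence D_XY and D_a; Hudson's
  F_ST = 1 − H_w/H_b with a permutation test; linkage disequilibrium
  |D′| with singleton-exclusion and minor-allele-frequency filters.
* **Site frequency spectra** — unfolded spectra ξ₁..ξ_{n−1} polarized on
  a designated outgroup (with a full log of unpolarizable sites), folding
  η_i = ξ_i + ξ_{n−i}, normalization, and explicit mode finding.
* **Coalescent models** — Kingman; the Beta(2−α, α) Λ-coalescent
  (λ_{b,k} = B(k−α, b−k+α)/B(2−α, α), 1 ≤ α ≤ 2, α = 2 ≡ Kingman); the
  point-mass (Dirac ψ) coalescent (λ_{b,k} = ψ^{k−2}(1−ψ)^{b−k}); and
  exponential / algebraic growth as time-changed Kingman models.
  Genealogy simulation by the block-counting chain (compiled core), exact
  expected total branch lengths by recursion, and expected normalized
  spectra φ_i = E[L_i]/E[T] (closed form 1/i for Kingman, cached Monte
  Carlo otherwise).
* **Model fitting** — minimum-ℓ² grid search,
  ℓ² = Σ (ξ_i/S − φ_i)², with the Kingman null ℓ²(0), likelihood-ratio
  G tests with right-tail pooling, and approximate multinomial
  log-likelihoods.
* **Synthetic data** — neutral single-population datasets under any of
  the models, and a two-haplogroup *balanced locus* generator whose
  preset emulates a 122-sequence, 2,500-bp locus split into divergent
  haplogroups of 43 and 79 sequences with ~20 diagnostic sites, a strong
  within-group singleton excess, and an outgroup at 2% divergence.

See `vignettes/multiple-merger-sfs.Rmd` for the models, conventions and
numerical choices, and `analysis/01_simulate.R` … `04_fit.R` for the
end-to-end workflow (each script writes its tables under `results/`).

## Worked example

```r
library(lambdasfs)

sim <- simulate_balanced_locus(preset_ckma_like())
aln <- sim$alignment
summary_stats(aln)
#> n=122 S=63 H=39 h=0.846 K=10.550 theta_S=0.0046865 pi=0.0042201 D=-0.314 (L_eff=2500)

sf <- unfolded_sfs(aln, "outgroup_1")
find_modes(sf, min_separation = 5)[1:3, ]
#>   class count
#> 1     1    31
#> 2    43     6
#> 3    79     6

labs <- classify_haplogroup(aln, sim$truth$diagnostic_column,
                            sim$truth$allele_map)
hudson_fst(aln, labs, n_perm = 1000, seed = 42)$estimate
#> [1] 0.9366722

fit_model(sf, "beta", reps = 2e4, seed = 211)
#> fit_result: beta best_param=1.37 l2_min=0.03076 l2(0)=0.1353 G=26.2 (df=4, p=2.86e-05)
```

Reading the output: the overall sample mixes two divergent haplogroups,
so π is inflated relative to θ_S and Tajima's *D* is only mildly
negative, while the unfolded spectrum is trimodal — a singleton mode plus
two high-frequency modes at the complementary haplogroup sizes 43 and 79,
the genealogical signature of a balanced polymorphism. The haplogroups
are strongly differentiated (F_ST ≈ 0.94 here; the permutation P is at
its minimum). The Beta(2−α, α) fit (α̂ = 1.37) beats the Kingman null by
a factor of ~4 in ℓ² by capturing the singleton excess, but no
single-parameter coalescent reproduces the two balanced modes — exactly
the pattern that flags balancing selection on top of sweepstakes
reproduction.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline pipeline from scratch — generates the
balanced-locus emulation at the given seed, computes summary statistics,
haplogroup F_ST, the unfolded spectrum, and the Beta- and Dirac-family
minimum-ℓ² fits against the Kingman null — logging the key quantities to
standard error and writing the JSON report to `--out`.
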