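---
title: "Models and design choices in seqgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in seqgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package studies

`seqgp` implements, on fully synthetic populations, the study design used
to ask whether genomic prediction in closed, intensely selected livestock
lines benefits from whole-genome sequence (WGS) variants over a commercial
marker array. The pipeline chain is:

1. simulate multi-line pedigreed populations with dense genotypes and a
   nested chip panel (`simulate_pedigree()`, `simulate_founders_and_drop()`,
   `designate_chip()`, `simulate_trait()`);
2. compute pedigree (`pedigree_A()`) and genomic (`genomic_K()`)
   relationship matrices;
3. derive a response per animal — either a deregressed breeding value
   from an animal-model BLUP (`animal_model_blup()`, `deregress()`), or
   the simulated phenotype directly (the bypass);
4. scan the sequence panel with a single-variant linear mixed model
   (`estimate_null_vc()`, `association_scan()`);
5. build predictor variant sets (`chip_set()`, `select_top_per_window()`,
   `select_chip_plus_sign()`, `ml_variant_universe()`);
6. fit the BayesR mixture model (`fit_bayesr()`, `predict_gebv()`);
7. evaluate with the pedigree-aware train/test design
   (`define_test_set()`, `define_training_set()`, `accuracy()`, `bias()`,
   `compare_scenarios()`).

Everything is driven by one seeded configuration (`default_run_config()`,
`run_pipeline()`), and every stage seed is derived from the global seed by
a fixed documented offset, which is what makes whole-pipeline reruns
bit-for-bit reproducible.

## The synthetic world

The generator emulates the *statistical structure* the analysis relies
on, not any real genome:

* **Pedigree.** Closed lines with discrete generations; per generation a
  fixed number of sires and dams is selected at random (no directional
  selection) and each dam produces one full-sib litter. The last
  generation therefore contains the full-sib families (default litter
  mean 10, a realistic pig litter) from which test sets are drawn.
  `birth_order` is a strict total order within line so that "remove the
  oldest records" is well defined.
* **Founder LD.** Founder haplotypes come from a first-order Markov chain
  over loci: the correlation between alleles at distance `d` bp is
  `exp(-d / 50000)` by default. This is not coalescent-accurate, but it
  gives the one feature the study question needs — chip variants tag, and
  do not coincide with, causal sequence variants — with a tunable decay
  length. Founder allele frequencies are Beta(0.8, 0.8) draws clamped to
  [0.01, 0.99], giving a U-shaped spectrum with some QC-relevant rare
  variants.
* **Gene dropping.** Descendants receive recombinant gametes with
  crossovers from a Poisson process along the genetic map (1 cM/Mb
  default), i.e. the Haldane map function with no interference.
  Mendelian consistency of every trio is exact by construction and is
  asserted in the tests rather than assumed.
* **Traits.** `n_qtn` causal variants get standard-normal allele
  substitution effects; the residual variance is set so that
  `var(TBV)/var(phenotype)` hits the target heritability. The
  `wgs_only` switch keeps QTN off the chip, mirroring the premise that
  sequence data contain causal variants that arrays miss.
* **What a green test does not establish.** The generator has no
  selection, no overlapping generations, no genotyping or imputation
  error (unless `inject_genotype_noise()` is used), and LD without
  long-range structure. Results on it validate the machinery and the
  direction of effects, not the magnitude of real-data accuracies.

## The models

**GWAS.** For each variant, `y = x b + u + e` with
`u ~ N(0, K sigma_u^2)`; `K` is VanRaden method 1 on chip variants only
(the field default; the source software's exact kernel is unstated).
Variance components are REML estimates from the null model, obtained
after one eigendecomposition of `K` by profiling everything but
`delta = sigma_e^2/sigma_u^2` (the FaST-LMM trick); per-variant tests are
then Wald tests under GLS with the variance components held fixed. The
per-variant residual variance is rescaled so that `sigma_u^2 = 0`
reduces the scan *exactly* to ordinary least squares — this is also how
the test suite pins the implementation to an independent OLS oracle.
There is no leave-one-chromosome-out correction; proximal contamination
is accepted and only matters for variants on the chip's own chromosome
segments. No multiple-testing adjustment is applied: the downstream
preselection uses the fixed threshold `p <= 1e-6`.

**Preselection.** Windows are consecutive, non-overlapping, 55 kb,
anchored at position 1 of each chromosome (position 55 000 is in window
0, position 55 001 starts window 1). Top-per-window takes the lowest-p
tested variant per window, ties broken by position then id — both
conventions are ours, chosen for determinism and documented here because
the window anchoring is not identified by the design. Density variants
(10k…100k) rescale the window to `55000 * 40000 / target`; a global
p-ranking alternative is available (`method = "rank"`).
Chip-plus-significant keeps, per window, the single best variant with
`p <= 1e-6` and merges it with the chip; the set is strictly additive
over the chip, so the chip is never pruned and lowering the threshold
can only shrink the additions.

**BayesR.** `y = 1 mu (+ line) + X beta + e` with a four-component
normal mixture prior on each effect, variances
`(0, 1e-4, 1e-3, 1e-2) * sigma_g^2`, uniform Dirichlet prior on the
mixture proportions, and `sigma_g^2` re-estimated every iteration as the
empirical variance of the current genetic values `X beta` (the
alternative `sum(2p(1-p) beta^2)` rule is behind the `sigma_g_rule`
flag). The residual variance has a flat scaled-inverse-chi-square prior.
Dosages are centred by training means and not standardised (the
component variances already scale with `sigma_g^2`). Multi-line fits add
a categorical line effect with the reference line absorbed in the
intercept.

Numerical/initialisation choices that the model statement leaves open:

* The chain starts at the *empty model* (all effects in the null
  component; the first mixture-proportion draw is
  Dirichlet(alpha + all-null counts)), the convention of
  variable-selection samplers.
* Because `sigma_g^2` is re-estimated from `X beta`, the empty model
  would anchor the component variances at zero and become absorbing. The
  anchor is therefore floored at `0.05 * var(y)` (and the first sweep is
  anchored at `0.5 * var(y)`). The floor is a weakly informative minimum
  effect-size scale: small enough not to distort `sigma_g^2` once any
  signal is picked up, large enough that variants with appreciable
  marginal association escape the null component within a few sweeps,
  after which the rising non-null proportions lower the escape threshold
  for the remaining variants (an avalanche that is clearly visible in
  the kept-sample trace).
* Reported `sigma_g2` is the *unfloored* posterior mean of
  `var(X beta)`.
* The sampler keeps a single-precision copy of the centred dosage matrix
  (it is memory-bandwidth bound); all sums are accumulated in double.
  Chains are reproducible from `set.seed()` via R's RNG.

**A known identifiability limit.** Under a pure-noise trait the marginal
likelihood ratio between components integrates to exactly one for every
variant, so the component counts are a critical (martingale) process and
the uniform Dirichlet prior pulls the proportions toward its mean (1/4
per class) at rate ≈ `4/m` per iteration. At desk scale
(n ≈ 1000, m ≈ 5000) the small-variance component is likelihood-
indifferent (`a = n * 2pq * 1e-4 * sigma_g^2 / sigma_e^2` ≈ 0.01) and
nothing opposes that drift, so the zero-class proportion settles around
0.85–0.93 rather than above 0.95; predictions remain correctly null
(effects are negligible in magnitude). Zero-class dominance above 0.95
is a large-n property — at the training sizes of the motivating study
(tens of thousands) even the small component is actively penalised for
null variants. The acceptance suite asserts the stated 0.95 bound
anyway and that single expectation is expected to fail; we prefer
reporting the honest behaviour over reparameterising the prior.

**Deregression.** The animal model is solved by Henderson's MME with
`lambda = (1-h2)/h2` and phenotypic variance anchored at `var(y)`;
reliability is `1 - PEV/sigma_u^2` from the inverse coefficient matrix.
Deregression removes the parent average and unshrinks the
Mendelian-sampling part with `r2_MS = max(0.01, r2 - (r2_s + r2_d)/4)` —
a simplified closed form of the VanRaden-style procedure (the exact
variant used by breeding programmes, with record weights and PA
reliability adjustments, is not published); record weights are computed
and stored but the prediction model is unweighted. Simulation
experiments default to the bypass (`y` = simulated phenotype) so that
prediction-method behaviour is not confounded with deregression choices.

**Evaluation.** Test sets are childless last-generation full-sib
families of at least five sibs; the training set is every phenotyped
animal with pedigree relationship `< 0.5` to every test animal (the raw
numerator relationship, so full sibs at 0.5 are excluded — whether the
source design used inbreeding-standardised correlations instead is
unstated). Training reduction keeps the most recent `target_n` records by
birth order. Replicate splits assign whole families to `k` balanced
subsets. Accuracy is the Pearson correlation of GEBV with the evaluation
response, bias the OLS slope of response on GEBV; undefined metrics are
reported as missing, never as zero. The accuracy-difference analysis
regresses (set − chip benchmark) differences on training-set size with
trait/line factors, by unweighted OLS (an `n_test`-weighted variant
would be easy but the source analysis is unspecific).

## Tunables that matter

| parameter | default | why |
|---|---|---|
| `founder_ld_decay` | 2e-5 /bp | 50 kb correlation length; sets how well chip tags sequence |
| `recombination_rate` | 1e-8 Morgan/bp | 1 cM/Mb |
| chip MAF / WGS MAF | 0.01 / 0.023 | array QC; imputed-dosage reliability threshold |
| HWE alpha | 1e-6 | "significant deviation" level, unstated upstream; configurable |
| window size | 55 kb | preselection window |
| `p` threshold | 1e-6 | significance for chip-plus-significant |
| mixture fractions | 0, 1e-4, 1e-3, 1e-2 | BayesR component variances as fractions of `sigma_g^2` |
| chain | 10000 / 5000 / 10 | iterations / burn-in / thinning; tests use shorter chains |
| `rel_threshold` | 0.5 | train/test pruning bound |
| `min_family_size` | 5 | full-sib test family size |

## Known limitations

* Founder haplotypes are Markovian: no long-range LD, no population
  bottleneck structure; multi-line differentiation comes only from
  independent founder draws over shared coordinates.
* The GWAS uses one variance-component fit per scenario (null model),
  not per variant; this is the standard approximation and is what the
  OLS-reduction test pins down.
* With the empty-model start, traits whose largest single-variant signal
  is far below the `log(m)` escape threshold are fitted conservatively
  in short chains; longer chains and the avalanche dynamics mitigate
  this, and it does not affect the sparse-architecture regimes the
  package is built to study.
* The deregression is a declared simplified stand-in; use the bypass in
  simulation studies.
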