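---
title: "Microbiome-mediated genome scans: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbiome-mediated genome scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(medipath)
```

## The question the framework answers

A conventional GWAS coefficient lumps together every causal route from a
variant to a trait. When the trait is also shaped by the gut microbiome, and
microbial abundances are themselves partly heritable, part of a marker's
total effect `γ` may travel through a microbial mediator. `medipath`
decomposes it: for a marker `G`, a CLR-transformed microbial feature `M` and
a standardized phenotype `P`,

```
M = α' G + nuisance + ε_m
P = β' M + γ' G + nuisance + ε_p
```

so the mediated effect is the product `α'β'`, the direct effect is `γ'`, and
with matched covariate sets the GWAS total satisfies `γ = γ' + α'β'`
*exactly* (an algebraic identity of least squares, which the test suite
asserts at 1e-10 relative error). The system is recursive — `M` never
depends on `P` — with uncorrelated equation errors, so equation-wise OLS
*is* the joint maximum-likelihood solution; the suite verifies this against
a brute-force numerical optimization of the joint Gaussian likelihood.

Causal language here rests on the usual mediation assumptions: no unmeasured
confounding of the `G→M`, `G→P` and `M→P` edges after conditioning on the
design covariates, and correct temporal ordering (microbes sampled before
the trait was expressed; the pipeline enforces this with a stage screen).

## Preprocessing compositional mediators

OTU counts, rarefied to a common depth upstream (a validator warns if row
sums are unequal), pass through three steps:

1. **Filtering** (`filter_otus()`): features with fewer than 1,200 total
   counts or a zero in more than 80% of samples are removed; both rules are
   evaluated jointly on the incoming counts.
2. **Zero replacement** (`replace_zeros()`): deterministic multiplicative
   replacement — each zero cell becomes `0.65 / depth` of the row's mass,
   nonzero cells shrink multiplicatively so rows stay compositions. A
   Bayesian-multiplicative imputation would also be defensible; the
   deterministic variant was chosen because it has one transparent,
   configurable parameter (`delta_fraction`) and no hidden prior, so runs
   are exactly reproducible.
3. **CLR** (`clr_transform()`): `log x - mean(log x)` per row, giving
   scale-invariant, unconstrained covariates whose rows sum to zero.

Table state is tracked, so a CLR table fed back into any earlier step is an
error rather than a silently corrupted re-transform.

## Collapsing the cross-classified design

SEM machinery dislikes factors with hundreds of levels, so nuisance
structure is absorbed in two steps per response (every trait *and* every
CLR feature): first a REML mixed model

```
y = CG + D + S + pen + ε        (pen random, everything else fixed)
```

fitted with `lme4` — contemporary group (12 levels by default: trial-week ×
sex batches), dam line coded numerically 1/2, sire (28), pen (331) — then
the collapsed covariates

```
CGb_i = CG-solution[i] + pen-BLUP[i]        Sr_i = sire-solution[i]
```

standardized to mean 0, SD 1. Standardization makes the covariates
invariant to the reference-level constraint used for the (rank-deficient)
fixed effects, which is why drop-first coding is safe. Each response gets
its own `(cgb_<response>, sr_<response>)` pair.

One property of this two-step scheme deserves emphasis: because `CGb` is
estimated *from the response*, it absorbs whatever share of a mediator's
effect lives at the CG/pen level. When microbial features themselves carry
contemporary-group or pen structure, a mediator's `β'` is estimated from
within-group variation only, and sits below the data-generating coefficient
by roughly the mediator's between-group variance share. This is a property
of the framework, not an estimation bug; the parameter-recovery tests
therefore use generator configurations whose microbial design variances are
zero, isolating the estimator itself.

## Association scans

`scan_association()` runs all three single-feature scans through one code
path (asserted by test): GWAS (`γ`), MWAS (`β`) and the genotype-to-microbe
scan (`α`). Each (response, feature) pair is an OLS fit of the standardized
response on the feature plus intercept, `CGb`, dam line and `Sr`; two-sided
t-tests use n − 5 degrees of freedom. The intercept is always included:
responses are standardized, but the covariates need not be exactly centered
in a finite sample. Covariates are projected out once per response
(Frisch–Waugh), so a scan over 40,000 markers is a single pass of matrix
algebra and numerically identical to the per-pair fit. Sporadically missing
dosages are mean-imputed per marker (call rates ≥ 0.99 upstream make the
effect negligible); monomorphic features are flagged `untestable` rather
than dropped. Bonferroni families are features-within-response, matching
the per-trait selection rule. `var_absorbed` is the population variance of
`β·M`, directly a proportion because responses have unit variance.

## Latent-variable models

Two latent fat-deposition constructs are the intended use: a growth factor
measured by three in-vivo backfat depths, and a terminal factor measured by
a final ultrasound depth, a post-mortem mechanical depth and the belly-cut
weight. `fit_sem()` fits Mod1L/Mod2L/Mod4L (and a plain CFA reduction) by
minimizing the ML discrepancy

```
F = log|Σ(θ)| + tr(S Σ(θ)⁻¹) − log|S| − k
```

over a RAM parameterization of all observed variables, mean structure
saturated. Choices that the data cannot decide, and how they were fixed:

* **Identification** — marker-variable convention: the first indicator's
  loading is fixed to 1 per construct. The standardized solution is
  reported by the tests, so results are invariant to which indicator is the
  marker (asserted by a reordering test).
* **Latent adjusters** — the three per-indicator `cgb` covariates load on
  one exogenous latent construct, the three `sr` covariates on another,
  loadings free, identified the same way; they enter the structural
  equation like ordinary predictors.
* **Exogenous block** — predictors (`G`, `M`'s covariates, dam line) are
  fixed exogenous observed variables whose covariance block is saturated
  (free parameters that converge to the sample moments), the
  conditional-ML convention.
* **Optimization** — quasi-Newton (L-BFGS-B) on log-scale variances from a
  sample-moment/OLS-informed start (a neutral fallback start is tried if
  the first is inadmissible), with a non-positive-definite Σ penalty.
  Uniqueness variances are bounded at zero by the log parameterization;
  estimates reaching the boundary are flagged as Heywood cases. Standard
  errors come from the inverse observed information (numeric Hessian of F,
  scaled by 2/n); a singular information matrix is reported, not hidden.
* **Degenerate constructs** — a single-indicator spec fixes loading 1 and
  uniqueness 0, making the latent identical to its indicator. In this limit
  Mod4L reproduces the measured-variable path model to 4 decimals, the
  bridge test between the two model families. With three near-noiseless
  indicators the latent regression collapses to OLS on the indicator mean
  (asserted at 1e-3).

The CFA reduction is cross-checked against `stats::factanal()` (an
independent ML factor-analysis implementation) at 1e-4 on standardized
loadings.

## Empirical significance

Sobel's normal approximation for a product is known to be poor, so the
confirmatory instruments are empirical, 1,000 rounds and 95% percentile
intervals by default:

* **Percentile bootstrap** (`bootstrap_test()`): resample whole records
  with replacement, refit, declare significance when 0 is outside the
  interval. BCa corrections were deliberately not layered on top: the
  procedure is the plain empirical interval, kept as described.
* **Path-breaking permutation** (`permutation_test()`): shuffle the
  mediator column only — severing `G→M` and `M→P` jointly while leaving
  the direct path intact — and declare significance when the observed
  indirect estimate falls outside the null interval. The permutation is
  unstratified, which also breaks mediator–covariate links; per-coefficient
  null draws are retained for audit.
* **Joint decision** (`joint_decision()`): a triple is a discovery only if
  both tests agree.

**Calibration caveat, worth knowing before trusting either test alone.**
The two instruments have different matched nulls. The bootstrap is
approximately nominal when one arm of the path is truly null (≈5–6% type-I
at α = 0, β ≠ 0 in the calibration study the acceptance suite runs), but it
is extremely conservative at the both-arms-zero point null, where the
product's sampling distribution collapses into a spike at 0. The
permutation test is calibrated against the null *it generates* — both arms
severed — and is markedly anticonservative when only `α = 0` but `β ≠ 0`,
because shuffling also destroys the live `M→P` arm and narrows the null
interval relative to the observed product's sampling spread. The joint
decision inherits the stricter of the two in each regime, which is the
practical reason for requiring both. The permutation target is the indirect
product itself (the screened and reported quantity), not the separate
coefficients.

## The discovery pipeline

`run_pipeline()` chains the stages deterministically under one seed:

1. preprocess and collapse (`mediation_data()`);
2. GWAS and MWAS scans;
3. **mediator selection**: Bonferroni-significant on *all three* traits of
   a factor's triplet, absorbing > 1% of variance on all three, and
   stage-compatible (a feature sampled at the third collection cannot
   mediate traits recorded at the second);
4. per-marker mediation scan for each selected (mediator, trait) pair;
5. **screens**: mediation ratio strictly > 1 (absolute-value convention, so
   opposite-sign masking mediation is retained; `γ' = 0` with a nonzero
   indirect counts as ratio ∞); total-effect candidates at `γ` p < 0.01 go
   to bootstrap only;
6. empirical testing of the screened triples, strongest (smallest Sobel p)
   first up to `max_candidates` — a desk-scale cap that bounds runtime and
   is configurable;
7. latent-model fits for the top markers per mediator (`latent_max_markers`);
   latent-path resampling is off by default (`latent_rounds = 0`, Sobel +
   ratio rule instead) because each SEM refit costs seconds, not
   microseconds;
8. tabulation (measured-only / shared / latent-only partition of discovered
   markers — exhaustive and disjoint by construction) and greedy grouping
   of discovered markers into windows of 10 consecutive genotyped SNPs per
   chromosome (panel-index space, not base pairs; the seed marker anchors
   each window). A generic BED-like interval-overlap counter
   (`count_overlaps()`) summarizes user-supplied annotation tables.

Every summary number is recomputable from the row-level records
(`summarize_discoveries()`), and a re-run with the same config and seed is
byte-identical.

## What the synthetic generator does and does not emulate

`simulate_cohort()` reproduces the statistical skeleton the framework
assumes: binomial(2, MAF) dosages with MAF uniform on [0.05, 0.5] over 18
autosomes; 12 contemporary groups with pens nested inside them (nesting
chosen because pens are physical batches within a trial week; 331 pens, 28
sires, binary dam line); latent log-abundances linear in dosage and design
effects mapped to counts by one multinomial draw per sample at depth
10,000 — so zero inflation arises purely from sampling low-proportion
features, with no separate hurdle process; and six traits loading on two
latent factors, with mediator effects entering the factor scores through
the *noise-free* CLR values. Default loadings (1, 0.9, 0.8 / 1, 0.8, 0.6)
and uniquenesses (0.35–0.6) give indicator correlations in the 0.5–0.8
range typical of repeated fat-depth measures; default nuisance variances
(CG 0.10, pen 0.05, sire 0.05, residual 0.55) put the design share of trait
variance near 25%. Effect sizes are not taken from any external source; the
defaults in the recovery and discovery studies were chosen so selected
mediators absorb on the order of 1–10% of trait variance.

Not emulated: linkage disequilibrium (markers are independent, so window
grouping exercises only the bookkeeping), pedigree relatedness,
longitudinal microbiome dynamics, and taxonomic structure. Passing tests
therefore demonstrate estimator and pipeline correctness under the model's
own assumptions — not robustness to LD, cryptic relatedness or
compositional artifacts beyond multinomial sampling noise. On that last
point: fitting on *observed* CLR values attenuates `α'` and `β'` slightly
(errors-in-variables from finite sequencing depth, plus the `(d−1)/d`
centering factor a planted per-feature effect acquires in a d-part
composition); the recovery tests quantify against the attainable targets.

## Problem sizes and numerical tolerances

The test and acceptance studies run at deliberately desk-friendly sizes:
calibration over 200 simulated cohorts of n = 400 with 500 resampling
rounds; recovery at n = 5,000 (paths) and n = 2,000 (loadings); the
end-to-end discovery study at n = 1,000, 2,000 markers, 50 features, 20
planted mediated markers, 200 rounds, with a matched null cohort expected
to produce zero joint discoveries. The full cohort preset
(`preset = "cohort"`: 1,183 individuals, 40,542 markers) is provided for
realistic-scale runs. Key tolerances: CLR row sums 1e-9; decomposition
identity 1e-10 relative; OLS-vs-joint-ML 1e-6; SEM discrepancy gradient
~1e-8 on the optimizer scale, CFA-vs-factanal 1e-4, degenerate-limit 1e-3.

## Known limitations

* One mediator at a time; multiple simultaneous mediators (and latent
  mediators) are out of scope.
* Equation errors are assumed uncorrelated; a hidden confounder of `M` and
  `P` would be read as mediation.
* No mixed-model GWAS with a polygenic term, and no LD-aware clumping — at
  realistic marker densities neighboring significant SNPs are summarized
  only by the index-window grouping.
* The permutation test's anticonservativeness under partial nulls (above)
  means its significance alone should not be reported; use the joint
  decision.
* Collapsed covariates absorb between-group mediator signal by design;
  effects expressed mostly between contemporary groups or pens are
  invisible to the framework.
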