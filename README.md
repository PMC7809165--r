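# medipath

Genome scans that look *through* the gut microbiome. `medipath` estimates how
much of a host genetic variant's effect on a quantitative trait is direct and
how much is transmitted by a microbial mediator, for both measured traits and
latent constructs built from correlated indicators.

The package grew out of swine fat-deposition genetics — cohorts of ~1,200
commercial pigs with SNP-chip genotypes, rarefied 16S OTU counts from fecal
swabs at several ages, six correlated fat-depth/belly-weight traits and heavy
cross-classified nuisance structure (contemporary groups, pens, sires, dam
lines) — but every component is generic tabular statistics: samples ×
variables in, tibbles out.

## The models

For marker dosage `G` (0/1/2), CLR-transformed microbial feature `M` and
standardized phenotype `P`, with collapsed design covariates `CGb`, `Sr` and
dam line `D`:

* **Total effect (Mod1, GWAS)** — `P = γ G + b₁ CGb + b₂ D + b₃ Sr + ε`
* **Microbial effect (Mod2, MWAS)** — `P = β M + b₁ CGb + b₂ D + b₃ Sr + ε`
* **Mediation path model (Mod4)** — the recursive pair

  ```
  M = α' G + b₁ CGbₘ + b₂ D + b₃ Srₘ + εₘ
  P = β' M + γ' G + b₁ CGbₚ + b₂ D + b₃ Srₚ + εₚ
  ```

  with indirect (mediated) effect `α'β'`, mediation ratio `|α'β'| / |γ'|`,
  and the exact decomposition `γ = γ' + α'β'` under matched covariates.
* **Latent variants (Mod1L/Mod2L/Mod4L)** — the same structure with `P`
  replaced by a latent factor Π measured by three indicators, adjusted by
  latent nuisance constructs built on the indicators' own `CGb`/`Sr`
  covariates, fitted by ML covariance-structure estimation.

Significance of the mediated path combines the deterministic Sobel test with
two empirical instruments: a percentile bootstrap over records and a
path-breaking permutation that shuffles the mediator column; a discovery
must pass both.

## Worked example

```r
library(medipath)

# a synthetic cohort with one planted chain: snp_3 -> otu_4 -> bf1
cohort <- simulate_cohort(sim_config(
  n_individuals = 400, n_markers = 8, n_otus = 10, n_pens = 60,
  effects = list(
    alpha = data.frame(marker = "snp_3", otu = "otu_4", effect = 0.5),
    beta  = data.frame(otu = "otu_4", response = "bf1", effect = 0.4),
    gamma = data.frame(marker = "snp_3", response = "bf1", effect = 0.1)),
  seed = 202))

dat <- mediation_data(cohort)   # filter -> zero-replace -> CLR -> collapse -> join

fit <- fit_mediation(dat, "bf1", "otu_4", "snp_3",
                     covariates_m = c("cgb_otu_4", "damline", "sr_otu_4"),
                     covariates_p = c("cgb_bf1",  "damline", "sr_bf1"))
fit
#> <path_fit> snp_3 -> otu_4 -> bf1 (n = 400)
#>   alpha' = 0.3182 (SE 0.0985), beta' = 0.2119 (SE 0.0449), gamma' = 0.0504 (SE 0.0950)
#>   indirect = 0.0674, ratio = 1.338

sobel_test(fit)
#> # A tibble: 1 × 2
#>       z p_value
#>   <dbl>   <dbl>
#> 1  2.66 0.00772
```

Each copy of the minor allele shifts the mediator by `α'` ≈ 0.32 on the CLR
scale; one CLR unit of the mediator moves the standardized trait by
`β'` ≈ 0.21; the resulting mediated effect (0.067 phenotypic SDs per
allele) exceeds the direct effect `γ'` ≈ 0.05 (ratio 1.34 > 1), so this
triple would enter empirical testing:

```r
fitter <- mediation_fitter("bf1", "otu_4", "snp_3",
                           c("cgb_otu_4", "damline", "sr_otu_4"),
                           c("cgb_bf1", "damline", "sr_bf1"))
bootstrap_test(dat, fitter, n_rounds = 1000, seed = 1)$significant    # TRUE
permutation_test(dat, fitter, "otu_4", n_rounds = 1000, seed = 2)$significant  # TRUE
```

`run_pipeline()` chains everything — preprocessing, covariate collapsing,
GWAS/MWAS scans, mediator selection (Bonferroni + >1% variance absorbed +
causal timing), the per-marker path scan, ratio screening, both empirical
tests, latent-model fits and 10-SNP window grouping — into one reproducible
`discovery_table`.

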