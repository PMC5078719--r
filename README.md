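# ltagmm

Latent transition analysis with growth-mixture measurement, in R.

## The problem

Children's reading ability does not grow along one smooth curve: skills
mastered early (letter knowledge, decoding) saturate around first grade,
while comprehension-type skills keep developing for years. A natural
model for a long panel of linked ability scores is therefore *piecewise*:
two developmental stages, a small number of latent ability groups within
each stage, and movement ("transition") between groups across the stage
boundary. `ltagmm` implements that model for applied researchers working
with wide-format longitudinal score panels:

* **Per-stage growth mixtures** — each stage's scores follow a K-class
  mixture of linear latent growth curves: class *c* has growth factors
  (intercept, slope) ~ N(μ_c, Ψ_c), observed scores
  y_t = intercept + t·slope + ε_t, fitted by multi-start EM with
  full-information handling of missing cells.
* **3-step transition model** — modal class assignments W are treated as
  error-prone indicators of the true classes through the
  classification-error matrix q_ks = P(W = s | C = k); the structural
  model (logistic Stage-1 membership, logistic Stage-2 membership per
  origin class, plus transition-specific covariate effects) is then
  estimated by maximum likelihood with q fixed:

      Σ_i log Σ_{g1,g2} P(g1|x_i) P(g2|g1,x_i) q1[g1,W1i] q2[g2,W2i]

* **Model selection** — −2LL, BIC, sample-size-adjusted BIC (primary),
  relative entropy, and a class-enumeration driver that screens out
  classes holding under 5% of the sample.
* **Multiple imputation** — joint-normal imputation of missing
  covariates with Rubin-rules pooling across imputations.
* **Synthetic cohort generator** — panels emulating a large
  kindergarten-to-Grade-8 reading cohort (n = 7803; realistic covariate
  moments and correlations, two-class growth structure per stage,
  upward-only transitions, sparse missingness), so the full pipeline is
  testable without any data download.

## Worked example

```r
library(ltagmm)

# a synthetic cohort at the packaged reference values
cfg   <- final_model_null(n = 7803, seed = 20161025)
panel <- generate_panel(cfg)
panel
#> panel_dataset: 7803 units, 7 indicators, 4 covariates
#>   missing cells: 2.46% overall (1789 units with any missing)
#>   truth labels present (synthetic panel)

specs <- stage_specs_for(cfg)
f2 <- fit_gmm(panel, specs$stage2, n_starts = 20, seed = 101)
print(f2)
#> gmm_fit: stage 2, K = 2, n = 7803
#>   loglik 992.657 (86 iterations, converged: TRUE)
#>   class weights: 0.951 0.049
#>   class 1: intercept 0.409, slope 0.119
#>   class 2: intercept -0.483, slope 0.189
```

The Stage-2 fit recovers the generating structure: 95% of children in a
high group starting at 0.41 on the linked ability scale and gaining 0.12
per year, 5% in a low group starting at −0.48 but gaining faster (0.19),
exactly the catch-up pattern the generator encodes. The full 3-step run
adds the transition table:

```r
res <- lta_3step(panel, specs, n_starts = 20, seed = 1)
res$step3$transition_matrix
#>       high   low
#> high 0.965 0.035
#> low  0.429 0.571
```

Children starting high essentially stay high; children starting low have
roughly even odds of moving up — the low-row probabilities estimate the
generating 0.474/0.526 after correcting for classification error. (The
Stage-1 grouping itself is weakly identified under these generating
values — the two Stage-1 classes overlap heavily — so proportion-type
estimates carry real sampling scatter; see the methods vignette.)

Covariate effects on membership and transition come from the same driver:

```r
res_cov <- lta_3step(panel_cov, specs,
                     covariates = c("parent_rating", "teacher_rating",
                                    "ses", "poverty"),
                     n_starts = 20, seed = 1)
res_cov$step3$pooled          # three coefficient blocks, Rubin-pooled
```

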