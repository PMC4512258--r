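# braim

Bayesian regression allelic imbalance modelling: detection of genomic
imprinting — parent-of-origin biased allelic expression — from
allele-specific RNA-seq expression estimates that carry measurement error.

## Who this is for

Transcriptomics researchers with allele-resolved expression estimates from
F1 reciprocal-cross designs (e.g. C57Bl/6J x Cast/EiJ hybrids) who want
per-transcript imprinting calls that account for (a) the posterior
uncertainty of the expression estimates themselves and (b) biological
variability across replicate animals, while controlling for cross, sex and
age effects.

## The model

For each transcript, the response in sample *j* is the posterior-mean
parental log-ratio over the S expression-posterior draws,

y&#770;_j = (1/S) &Sigma;_s [ log(TPM_j^(s)(pat) + c) − log(TPM_j^(s)(mat) + c) ],

with per-sample measurement-error variance ε̂_j (the posterior variance of
the same quantity) and detection floor c = 0.01 TPM. After scaling to unit
standard deviation, the response is modelled with a latent true response z:

- y&#770;′ | z ~ MVN(z, E),  E = diag(ε̂′)   (measurement error)
- z | β, σ² ~ MVN(Xβ, σ²I)                 (biological variability)
- β_i | σ², δ_i ~ N(0, σ²(τ c^δ_i)²),  δ_i ~ Bern(p)   (spike-and-slab)
- σ² ~ IG(ν/2, νλ/2)

X is ±1-coded: intercept = parental bias, then cross, sex, age (+1 for
F1i/male/P8). A Gibbs sampler (10,000 sweeps, 1,000 burn-in) draws
z → β → σ² → δ; the posterior probability (PP) of an effect is the mean of
its retained δ draws, significant at PP > 0.95. The paternal expression
fraction is the logistic of the unscaled parental coefficient. Defaults:
τ = 0.1, c = 4.25, ν = 2.5, λ = 0.04, p = 0.1.

Around the core model the package provides the full workflow: combined and
per-age fits with the three imprinting calling rules, combining of lowly
identifiable transcripts by posterior anti-correlation (cutoff −0.25 on
both alleles), imprinted-cluster assignment with 85:15 centers and a
bias-vs-distance decay regression, one-at-a-time hyperparameter sensitivity
analysis scored by ROC/AUC, and a synthetic cohort generator for
end-to-end validation.

## Worked example

```r
library(braim)

design <- sim_design(6)                                   # 48 samples, balanced
specs  <- sim_transcript_specs(n_transcripts = 40, n_imprinted = 8, seed = 5)
sim    <- simulate_cohort(specs, design, seed = 7)

wf <- run_fit_workflow(sim$posteriors, design, braim_hyper(seed = 11))
recovery_report(wf$calls, sim$truth)
#> # A tibble: 1 × 7
#>      tp    fp    tn    fn sensitivity specificity fraction_mae
#>   <int> <int> <int> <int>       <dbl>       <dbl>        <dbl>
#> 1     8     0    32     0           1           1       0.0246

dplyr::filter(wf$calls, imprinted)[1:2, 1:5]
#> # A tibble: 2 × 5
#>   transcript_id gene_id imprinted preferred_allele paternal_fraction
#>   <chr>         <chr>   <lgl>     <chr>                        <dbl>
#> 1 tx0001        g0001   TRUE      paternal                     0.794
#> 2 tx0002        g0002   TRUE      maternal                     0.102
```

All eight simulated imprinted transcripts are recovered with no false
positives; the estimated preferred-allele fractions track the simulated
ones to ~0.02 mean absolute error. `tidy()`, `glance()` and `autoplot()`
methods summarise and plot fits and calls; `run_sensitivity()`,
`combine_transcripts()` and `assign_clusters()`/`decay_regression()` cover
the surrounding analyses. A command-line front end is installed at
`inst/exec/braim` (`braim fit`, `simulate`, `combine`, `clusters`,
`sensitivity`).

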