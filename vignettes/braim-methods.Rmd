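---
title: "Detecting genomic imprinting with a measurement-error spike-and-slab regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic imprinting with a measurement-error spike-and-slab regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genomic imprinting is the epigenetically driven preferential expression of
one parental allele of a gene. Detecting it from RNA-seq in F1 hybrids of
reciprocal crosses (C57Bl/6J x Cast/EiJ and the reverse) is attractive
because the crossing direction separates parent-of-origin effects from
strain effects — but two sources of uncertainty conspire against naive
tests. First, allele-specific expression estimates are themselves uncertain:
an expression estimator that resolves reads between alleles and isoforms
reports a *posterior distribution* of TPM per transcript, allele and sample,
not a point value. Second, expression varies biologically across animals, so
replicate-poor designs that pool reads per cross confound biological
variability with allelic signal. `braim` implements a Bayesian regression
allelic imbalance model that addresses both: the response carries a known
per-sample measurement-error variance taken from the posterior spread, and a
latent "true" response with its own variance captures biological
variability across the cohort.

## The model

For transcript-level posterior draws $\mathrm{TPM}_j^{(s)}$ (draw $s$ of
$S$, sample $j$ of $n$), the default (difference) response is the posterior
mean parental log-ratio

$$\hat y_j = \frac{1}{S}\sum_s \left[\log(\mathrm{TPM}_j^{(s)}(\text{pat}) + c)
  - \log(\mathrm{TPM}_j^{(s)}(\text{mat}) + c)\right],$$

with $c = 0.01$ TPM the minimum detectable expression (a transcript-sample
whose posterior *median* is below $c$ has all draws replaced by $c$; the
constant also keeps the log finite). The posterior variance of the same
quantity (denominator $S-1$) is the measurement-error variance
$\hat\varepsilon_j$. Because coefficient scales must be comparable across
transcripts, $\hat y$ is divided by its across-sample standard deviation;
error variances are divided by the variance, since variances transform with
the square of a scale factor — the only convention that leaves the
likelihood consistent after scaling. Zero error variances — floored transcripts — are clamped to
$10^{-8}$ so the error covariance stays invertible; at that magnitude the
latent response is pinned to the data and the clamp has no statistical
effect.

The scaled response $\hat y'$ is modelled with a latent true response $z$:

$$\hat y' \mid z \sim \mathrm{MVN}(z, E), \qquad
  z \mid \beta, \sigma^2 \sim \mathrm{MVN}(X\beta, \sigma^2 I),$$

where $E = \mathrm{diag}(\hat\varepsilon')$ and $X$ is the $\pm 1$-coded
design: an all-ones intercept column whose coefficient is the parental bias,
then cross, sex and age columns coded $+1$ for F1i, male, P8 and $-1$ for
F1r, female, P60. In a balanced design $X^\top X = nI$, so effects are
orthogonal.

Each coefficient carries a spike-and-slab mixture controlled by a binary
inclusion indicator $\delta_i$:

$$\beta_i \mid \sigma^2, \delta_i \sim
  N\!\left(0,\ \sigma^2 (\tau_i c_i^{\delta_i})^2\right), \qquad
  \delta_i \sim \mathrm{Bernoulli}(p_i),$$

and $\sigma^2 \sim \mathrm{IG}(\nu/2, \nu\lambda/2)$. The $\sigma$-scaled
form of the coefficient prior is the one consistent with the inverse-gamma
conditional having shape $(n+p+\nu)/2$ and a $\beta^\top D_\delta^{-1}\beta$
term in its scale; an unscaled variant of the prior (without the
$\sigma^2$ factor) would be incompatible with that conditional, so the
$\sigma$-scaled form is used throughout. Similarly, the diagonal of
the coefficient prior covariance is used as a variance
$(\sigma\tau_i c_i^{\delta_i})^2$, the dimensionally consistent reading.

## Gibbs sampling

The four conditionals are conjugate and sampled in the order
$z \to \beta \to \sigma^2 \to \delta$:

* $z$: elementwise normal with precision $1/e_j + 1/\sigma^2$, a
  precision-weighted compromise between the observed response and the
  regression mean;
* $\beta$: multivariate normal with precision
  $X^\top X/\sigma^2 + (\sigma^2 D_\delta)^{-1}$;
* $\sigma^2$: inverse gamma with constant shape $(n+p+\nu)/2$;
* each $\delta_i$: Bernoulli with odds set by the spike/slab density ratio
  at the current $\beta_i$, computed in log space with probabilities clamped
  to $[10^{-12}, 1-10^{-12}]$. At $\beta_i = 0$ the ratio equals $c_i$, so a
  null effect is included with probability $p/(p + c(1-p)) \approx 0.026$ at
  the defaults.

The sampler runs 10,000 sweeps and discards the first 1,000 as burn-in; the
posterior probability (PP) of an effect is the mean of its retained
$\delta$ draws, and an effect is called significant at PP > 0.95.
Initialization is the data-centred, prior-neutral state $z = \hat y'$,
$\beta = 0$, $\sigma^2 = 1$, $\delta = 0$; the sampler is insensitive to
this choice because burn-in absorbs the transient. Each transcript gets an independent
RNG stream derived from the global seed and a hash of its id, so results are
identical regardless of fitting order. The production chain is compiled
(C++) but consumes R's RNG in exactly the order of the exported R
conditional-draw functions, so the two engines are interchangeable and are
tested against each other draw for draw.

Correctness is checked against two independent oracles: exhaustive
enumeration of all $2^p$ inclusion configurations (each marginal is a
multivariate t once $z$, $\beta$, $\sigma^2$ are integrated out, valid in
the zero-measurement-error limit), and the closed-form conjugate regression
posterior with $\delta$ held at all-ones.

## Hyperparameters

| parameter | default | meaning |
|---|---|---|
| $\tau$ | 0.1 | spike scale, per effect (relative to $\sigma$) |
| $c$ | 4.25 | slab multiplier: how much larger a real effect is |
| $\nu$ | 2.5 | variance-prior location; must exceed 2 |
| $\lambda$ | 0.04 | variance-prior scale, $\tfrac{2\mathrm{var}(\hat y')}{5}\cdot\tfrac1\nu(\tfrac\nu2-1)$ at unit response variance |
| $p$ | 0.1 | prior inclusion probability per effect |

$\lambda$'s formula is grouped as written above because it is the only
grouping that evaluates to 0.04 at $\nu = 2.5$ and unit variance.
Robustness to these empirical choices is assessed by a one-at-a-time
sensitivity analysis (`run_sensitivity()`): each parameter is perturbed to
four alternative values, the model refitted with everything else fixed, and
the perturbed parental-PP ranking scored by rank-based ROC/AUC against the
unperturbed significant calls. The same MCMC seed is reused across
perturbations so ranking differences reflect hyperparameters rather than
Monte-Carlo noise. Shrinking $\tau$ far below its default collapses both
mixture components and is the one direction that degrades the ranking
noticeably at desk scale; all other perturbations leave it essentially
intact.

## Calling rules and parental fractions

The combined fit (all 48 samples; cross, sex, age) is complemented by
independent P8-only and P60-only fits (cross, sex). A transcript is called
imprinted when (i) its combined parental PP exceeds 0.95; (ii) it is
expressed exclusively in one age group — every sample of the other age
floored — with parental PP > 0.95 in that group's fit; or (iii) its
combined age PP exceeds 0.95 and its parental PP exceeds 0.95 in either
single-age fit. Rule (iii) exists because a strong bias present at only one
age can null out the combined parental PP.

The parental coefficient mapped back to the unscaled response
($\hat\beta = $ posterior mean $\times$ scale factor) is the mean paternal -
maternal log-ratio, so the paternal expression fraction is the logistic
$e^{\hat\beta}/(1+e^{\hat\beta})$ — the unique normalisation under which
the paternal and maternal fractions are both proportions and sum to one. The
preferred-allele bias is the larger fraction, always in $[0.5, 1]$.
Posterior means are used as point estimates; medians are available from the
retained draws when needed.

## Transcript combining

Highly similar isoforms are not distinguishable by read data; their
posterior draws become strongly anti-correlated within samples. Within each
gene, pairs of units whose mean per-sample Pearson correlation (over
aligned draws) is below -0.25 on *both* alleles are merged iteratively —
most-negative pair first, correlations recomputed after each merge — until
no pair qualifies. Requiring both alleles keeps the merged unit identical
across alleles and therefore testable for parental bias. Merged draws are
elementwise sums: under read-assignment ambiguity the summed abundance is
the well-identified quantity, and the sum of anti-correlated draws has
smaller posterior spread than either member. Among the candidate
arithmetics (sum, average, re-estimation), summation is chosen for the
conservation and variance-reduction properties above, both of which are
tested.

## Cluster decay

Genes are represented by their isoform with maximal parental PP (ties:
larger $|\hat\beta|$, then lexicographic id). After strand normalisation
(antisense genes' start/end swapped to sense orientation) each chromosome
is scanned 5' to 3', chaining genes whose start is within 1 MB of the
previous gene's end. Genes with bias at or above 85:15 are candidate
centers; consecutive candidates group into one center interval; clusters
with several center groups split into sub-clusters at midpoints between
groups (1 MB beyond the extremes), and genes more than 1 MB from their
center are removed. Distance is measured from the gene's start site to the
nearest edge of the center interval (0 inside it): the removal rule is
phrased on start sites, and a grouped center is an interval, so
start-to-edge is the coherent anchor. Clusters with no qualifying center
keep their membership but take `NA` distances and are excluded from the
decay regression, which is a pooled OLS of bias on distance over non-center
members with a shared slope (a cluster-level random term is not included;
the pooled fixed-effect slope is the quantity of interest and the desk-scale
cohorts are too small to identify more).

## The synthetic cohort generator

`simulate_cohort()` mirrors the generative assumptions of the model: a true
per-sample log-ratio $d_j \sim N(x_j^\top\beta_{true}, \sigma^2_{true})$
placed symmetrically around a baseline log expression (so bias is
unconfounded with overall expression), and lognormal posterior draws per
allele emulating estimation spread, with the floor constant subtracted so
the round trip through $\log(\cdot + c)$ is exact. The default conditions —
500 transcripts of which 50 carry $|\beta_{parental}| \ge 1$ (uniform
magnitude in $[1, 3]$, random sign), a balanced 48-sample design,
$\sigma^2_{true} = 0.25$, measurement sd 0.1, $S = 100$ draws — are the
package's standing validation conditions; baseline log-TPM is drawn
$N(2, 1)$, a realistic mid-expression range well above the floor. What the
generator does *not* emulate: isoform-level posterior correlation structure
beyond the simple shared-reads split used to exercise the combiner,
library-size and GC artefacts, and mapping bias between alleles. Passing
recovery tests therefore demonstrate correctness of the inference given the
model's assumptions, not robustness to real-data artefacts upstream of the
expression estimates.

## Numerical choices and problem sizes

Density ratios are computed in log space; Bernoulli probabilities are
clamped; the coefficient precision is factored by Cholesky (symmetric
positive definite by construction). Responses constant across samples are
flagged un-fittable and skipped with a message. The validation suite runs
the exact-enumeration oracle at $n \le 6$, $p \le 2$ with 30,000 sweeps,
and the cohort-scale checks at 500 transcripts x 48 samples with the
default 10,000 sweeps — sizes chosen so the full suite completes in
minutes on a single core while leaving Monte-Carlo error well below the
tolerances tested.

## Known limitations

* The exact-enumeration oracle requires negligible measurement error; with
  large heteroscedastic errors only the Gibbs path is available.
* Single-allele response modes put the (large) mean log expression in the
  intercept; through the $\sigma$-scaled prior this inflates $\sigma^2$ and
  can damp the PPs of secondary effects. The difference response does not
  have this issue and remains the default.
* The PP cutoff is a fixed decision rule; no FDR control across transcripts
  is attempted.
* Convergence is handled by a fixed burn-in, matching the procedure the
  model was designed for; no adaptive diagnostics are run.
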