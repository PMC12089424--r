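---
title: "Variance explained in cognition under outcome measurement error: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance explained in cognition under outcome measurement error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Studies of Alzheimer's disease biomarkers often summarize their importance as
the proportion of variance they explain in cognitive outcomes. Cognitive
scores, however, are estimates of a latent trait and carry measurement error.
In a regression of an observed score on biomarkers, that error lands in the
residual: the residual variance is inflated by the average squared standard
error of measurement (SEM), so the variance-explained ratio is attenuated.
When scores come from item response theory (IRT) scoring, each person has
their own SEM — the posterior SD of their latent trait — and the error is
*heteroscedastic*: people whose ability sits where the test battery carries
little information are measured much more noisily. A single reliability
coefficient cannot represent this; a model that consumes the per-person SEMs
can.

`cogvarme` implements that correction as a reusable pipeline, plus a
synthetic cohort generator with fully known ground truth, so every stage can
be verified by parameter recovery without access-controlled data.

## The two regression models

Let $y_i$ be person $i$'s observed cognition score and $s_i$ their known SEM.
With regressors $x_i$ (a study-phase indicator, one or more biomarker
z-scores, and a PET-tracer indicator whenever amyloid burden is a regressor):

**Standard model** (`fit_standard`) treats the observed score as truth:
$$ y_i = x_i^\top \beta + \epsilon_i, \qquad \epsilon_i \sim N(0, \sigma^2). $$

**Measurement-error model** (`fit_me`) adds a latent true score
$\eta_i$ with a known observation-error SD:
$$ y_i \sim N(\eta_i, s_i^2), \qquad \eta_i \sim N(x_i^\top \beta, \sigma^2). $$

In the standard model $\sigma^2$ absorbs both residual trait variance and
measurement-error variance; in the measurement-error model $\sigma^2$ is the
variance neither captured by the predictors nor attributable to measurement
error. Rows with $s_i = 0$ are treated as observed without error (the latent
state equals the observation), the natural limit of the model.

Priors follow the weakly informative defaults of mainstream Bayesian
regression software: improper flat priors on slopes, Student-$t(3, 0, 2.5)$
on the intercept, Student-$t(3, 0.4, 2.5)$ truncated to positives on
$\sigma$. Sampler defaults are 3 chains of 1000 iterations with the first
200 discarded, and summaries are refused unless every parameter passes a
split-chain $\widehat{R} < 1.05$ gate (`convergence_ok`, enforced by
`run_study`).

## Headline quantities

Per retained draw $d$ the proportion of variance explained is the bounded
Bayesian R-squared
$$ R^2_d = \frac{\operatorname{var}_i(x_i^\top \beta_d)}
   {\operatorname{var}_i(x_i^\top \beta_d) + \sigma_d^2}, $$
which, unlike the naive predicted/observed variance ratio, lies in $[0, 1)$
for every draw (`bayes_r2`). Measurement-error variance is estimated by the
per-paired-draw difference of residual variances between the two fits
(`me_variance`); individual draws (and interval bounds) may be negative.
Method comparisons (`compare_methods`) report the per-draw absolute
difference $R^2_{\text{me}} - R^2_{\text{std}}$ and percent increase
$100\,(R^2_{\text{me}} - R^2_{\text{std}})/R^2_{\text{std}}$. The absolute
difference is linear, so its posterior mean equals the difference of means;
the percent increase is not, and is deliberately computed per draw. Draws of
the two independently fitted models are paired by retained-draw index over
pooled chains — the standard Monte Carlo construction when no joint
posterior couples them. Intervals are equal-tailed 2.5/97.5 percentiles
using linear interpolation of the empirical CDF (R's type-7 rule), and point
estimates are posterior means.

Because the expected attenuation has a closed form — with latent predictor
variance $V_p$, latent residual variance $V_r$ and mean squared SEM $m$, the
standard method converges to $V_p/(V_p + V_r + m)$ and the corrected method
to $V_p/(V_p + V_r)$ — the whole pipeline is testable by parameter recovery,
and the acceptance suite does exactly that.

## Sampling: why the Gibbs steps are collapsed

The conditional structure of the measurement-error model is fully conjugate
except for $\sigma$, which invites a Gibbs sampler updating $\beta$, each
$\eta_i$, and $\sigma$ (Metropolis) in turn. Implemented literally, that
sampler mixes poorly exactly where the correction matters: when $\sigma$ is
small relative to the SEMs, the latent states pin the parameters (and vice
versa), and at 3×1000 iterations the intercept and $\sigma$ showed
$\widehat{R}$ up to ~1.1 — tripping the pipeline's own convergence gate.

The sampler therefore works against the *exact marginal* of the latent
layer, $y_i \sim N(x_i^\top \beta, \sigma^2 + s_i^2)$: $\beta$ keeps a
closed-form normal conditional (GLS-weighted, with the Student-$t$ intercept
prior entering through its normal/inverse-gamma scale-mixture
representation, itself Gibbs-updated), and $\sigma$ gets an adaptive
random-walk Metropolis step on $\log \sigma$ (step size tuned during warmup
toward ~20–50% acceptance, then frozen). Latent true scores are redrawn from
their exact conditional after each update when requested
(`keep_latent = TRUE`) — a partially collapsed Gibbs scheme that samples the
identical joint posterior with standard-model mixing quality. Correctness is
anchored to two independent oracles rather than to any particular sampler: a
brute-force grid evaluation of the marginalized posterior
(`grid_me_posterior`, feasible at tiny $n$) and a deterministic
profile-likelihood GLS fit (`marginal_gls_fit`).

## IRT measurement

Scores are produced under the graded response model,
$P(Y_{ij} \ge k \mid \theta) = \operatorname{logistic}(a_j(\theta - b_{jk}))$,
with binary items as the two-parameter special case. EAP scoring integrates
over a quadrature grid against a standard-normal prior; the reported SEM is
the posterior SD of $\theta$ (the quantity released alongside published
cognitive composites and the one the regression model consumes), not the
information-based $1/\sqrt{I(\theta)}$ — though the two agree within ~10%
for long banks, and a property test checks this. Degenerate response
patterns (all items in one category) need no special casing: the prior keeps
the posterior proper.

Two numerical choices matter:

* **Grid**: 101 equally spaced nodes on $[-5, 5]$ with normal-prior weights
  and *trapezoid end-weights*. Common IRT software uses ~61 nodes, but
  posteriors under a long, highly discriminating bank can be narrow enough
  (SD ~0.1), and edge-reaching posteriors lose an order of convergence to
  the domain truncation, that 61 plain-Riemann nodes miss the package's
  1e-4 agreement contract with a 10,001-node reference integration. With
  101 trapezoid-weighted nodes the worst observed disagreement across 300+
  stress patterns is ~2e-5.
* **Standardization**: `standardize_scores` uses the population-SD
  (denominator $n$) convention for fixing a reference scale, while `zscore`
  (for biomarker columns) uses the usual $n-1$ sample SD. The difference is
  immaterial at cohort sizes but is fixed and documented so results are
  bit-reproducible.

The `sem_curve` function reports, per grid node, the test information and
the EAP-based SEM of a hypothetical respondent whose expected responses
arise at that node (realized through the expected log-likelihood
pseudo-pattern) — the standard visualization of how precision varies over
the trait.

## The synthetic cohort: what it emulates, and what it does not

`cohort_spec()` defaults describe a clinical aging cohort with stratified
recruitment: 482 cognitively normal (CN), 430 MCI, and 172 AD participants;
latent cognition $\theta \sim N(0.86, 0.47^2)$, $N(0.19, 0.51^2)$,
$N(-0.79, 0.36^2)$ by group; and six biomarkers (white matter
hyperintensity burden, amyloid, entorhinal thickness, hippocampal, medial
and lateral temporal volumes) whose per-group means and SDs on the
full-sample z-score scale match published cohort summaries. Each biomarker
additionally loads on latent cognition within group (loadings −0.2 to 0.45,
signed so more pathology accompanies worse cognition), giving within-group
correlations and full-sample univariate latent R² spanning roughly
0.05–0.35. Per-group residual SDs are *derived* from the target group SDs,
$\sqrt{\text{sd}_g^2 - \lambda^2 \text{sd}_{\theta,g}^2}$, so the stated
group SDs are exact in expectation; because the published summaries were
standardized on the full sample, the full-cohort z-score invariant
(mean ≈ 0, SD ≈ 1) follows automatically. The generator records the exact
latent R² realized in each cohort (least-squares projection of true
cognition on each regressor set) for recovery tests.

Two default item banks reproduce the battery-precision contrast that drives
the headline result: a "memory-like" bank (29 binary items, $a \in [1, 2.5]$,
$b \in [-2, 1]$) and a "visuospatial-like" bank (6 easy items,
$a \in [0.8, 1.5]$, $b \in [-2.5, -1]$), the latter producing a strong
ceiling effect, several-fold larger SEMs, and correspondingly larger
corrections.

Choices the data do not pin down, made once: study-phase split (0.6/0.4) and
tracer split (0.7/0.3), both *null* covariates in the generator (phase and
tracer have no effect on cognition, matching the adjustment-covariate role
they play in the models); tracer is drawn independently of phase even though
one tracer is phase-specific in the emulated study; white matter volumes of
exactly zero are mapped to $\log(\delta)$ with $\delta = 0.001$ cc before
log-transformation (volumes are physically positive; zeros only arise from
segmentation rounding). Intracranial-volume adjustment regresses volume on
ICV — method prose sometimes states the reverse direction, which is exposed
behind `direction = "icv_on_volume"` but not recommended, since only
volume-on-ICV makes the adjustment formula sensible.

What the generator does **not** emulate — and therefore what a green test
does not establish: real item parameters (published batteries mix
dichotomous and polytomous items with unknown calibrations), longitudinal
decline, measurement error in the biomarkers themselves, non-normal latent
distributions, informative missingness (the pipeline is complete-case with a
logged drop count), or recruitment processes beyond fixed group counts.
Qualitative reproductions (battery-size ordering of corrections; full-sample
versus stratified R²) are structural properties of the generator's world,
not numeric reproductions of any external dataset.

## The study pipeline

`run_study` executes the full factorial — per-biomarker and all-biomarker
models, both methods, full sample and per diagnostic stratum — with
biomarkers z-scored on the *full* sample before stratification (so strata
share a scale; this changes stratum-level coefficients and is deliberate),
per-cell sampler seeds derived from the study seed, and the $\widehat{R}$
gate as the mechanism that flags non-convergent cells (low-precision
batteries within strata are attempted, not pre-excluded; the gate decides).
Stratified fits reuse the full-sample priors. Every run is stamped with an
MD5 hash of its configuration and its seed, and rerunning with the same seed
reproduces the tables bit-for-bit.

## Known limitations

* The percent-increase summary is unstable when the standard-method R² is
  near zero (its draws are excluded only when exactly zero); interpret the
  interval, not just the mean, in that regime.
* With severely mis-scaled SEMs (e.g. a battery so weak that
  $\bar{s}^2$ approaches the total score variance) the measurement-error
  model is close to non-identified; $\sigma$ piles up near zero and the
  corrected R² approaches its upper limit. The fits converge, but the
  correction inherits the (mis)stated SEM scale — the model corrects for
  the error you declare, it cannot audit it.
* Biomarker measurement error is not modeled; coefficients and R² are
  conditional on biomarkers as measured.
* The grid oracle is exponential in dimension and supports only the
  one-regressor model; multi-regressor correctness rests on the GLS oracle
  and recovery tests.
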