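---
title: "Structural-after-measurement estimation with Croon corrections: models, corrections, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SAM-Croon methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samcroon)
```

## The problem

Structural equation models with latent interactions are notoriously hard to
estimate with full-information methods when the number of clusters is small
(tens rather than hundreds): numerical integration over latent products is
expensive, convergence failures are common, and estimates can be unstable.
Structural-after-measurement (SAM) estimation sidesteps this by splitting the
problem: fit a small measurement model per latent variable, predict factor
scores, and estimate the structural (path) model from the factor-score moment
matrix.  Uncorrected factor-score regression (SAM-FS) is simple but
attenuates structural coefficients, because regression factor scores are
shrunken measurements of the latent variables.  The Croon method-of-moments
correction (SAM-Croon) disattenuates the score moment matrix using the
measurement-model-implied unreliability before the structural step, the
multi-variable analogue of the classical correction for attenuation.

`samcroon` implements both estimators for

* two-level SEMs in which a latent moderator `Z` modifies the effect of a
  latent focal predictor `X` on a latent outcome `Y`, with the interaction
  located at the within level (`X^W * Z^W`), across levels (`X^W * Z^B`), or
  at the between level (`X^B * Z^B`); and
* 2/1 partially nested designs (clustered treatment arm, unclustered control
  arm) with latent moderated mediation: a treatment-level moderated b path,
  mediation effect `ME = a(t) * B(t)`, and a main effect defined as the
  conditional latent outcome intercept contrast.

## Measurement models and factor scores

Each latent variable gets a single-factor model per level.  Within-level
models are fitted to the pooled within-cluster covariance of the centered
indicators; between-level models to the covariance of the cluster means (the
univariate cluster-means route for estimating between-level indicator
components).  With three indicators the one-factor model is just-identified,
so the ML solution is closed form and reproduces the sample covariance
exactly; for other indicator counts a quasi-Newton optimizer on a
log-variance parameterization is used, with a second start on failure.

Fits are reported on the marker scale (first loading fixed at 1, factor
variance free).  This is a pure reparameterization of the unit-variance
identification, but it matters for the outcome: the latent outcome's marginal
variance is model-implied (not 1), and carrying its scale through the
pipeline is what makes the corrected structural coefficients land on the
generating scale.  Fixing every corrected variance to 1 instead would return
coefficients standardized by the outcome's model-implied SD and break the
package's population-consistency checks.

Regression factor scores use `A = psi Lambda' Sigma^-1`; the validity
`c = A Lambda` is the attenuation multiplier: the covariance of two scores is
`c_g c_h` times the latent covariance, which is exactly what the correction
divides away.

### Admissibility statuses

Measurement fits report one of:

* `converged` — proper solution;
* `heywood` — some residual-variance estimate is non-positive; estimates are
  still produced and usable for scoring.  Full-SEM software likewise reports
  such solutions (with a warning) rather than failing, and the simulation
  evidence (uncorrected-estimator failure rates of zero at reliabilities
  where Heywood cases are demonstrably a few percent) shows this is how such
  pipelines behave in practice;
* `boundary` — no real, finite factor solution exists (sign-inconsistent or
  degenerate covariances, no common variance);
* `non_PD` — the input covariance matrix is not positive definite.

The pipeline's convergence-failure event is: any `boundary`/`non_PD` fit,
or — for SAM-Croon only — an inadmissible corrected moment matrix (non-PD
predictor block, non-positive corrected variance, validity below `1e-3`, or a
negative implied residual variance).  Monte Carlo metrics are computed over
converged replications only; failure rates over all replications.

## The Croon correction as implemented

Given the raw score moment matrix at a level:

* covariance of two latent-variable scores: divided by `c_g c_h`;
* score variances: replaced by `(var(score) - A' Theta A) / c^2`, the
  measurement-implied factor variance (equals 1 for the unit-variance
  exogenous predictors in the population, and recovers the outcome's scale);
* covariance of the interaction score product with any variable: divided by
  the product of the three validities involved;
* the interaction variance is rebuilt from corrected first-order moments by
  the normal-theory product rule `var(ab) = var(a) var(b) + cov(a, b)^2`
  (evaluated at corrected, not raw, inputs — this is what makes the
  correction an exact inverse of attenuation);
* covariances between a product and its own parents are kept as corrected
  empirical quantities (population value 0 under normality); an option
  (`zero_product_covariances`) forces them to 0 instead.

### Between level: cluster means and their reliability

Cluster means carry a within-level sampling component of order `1/n1`.  Its
per-indicator size is summarized by the cluster-mean reliability
`R^B = (lambda_B^2 psi_B + theta_B) / (lambda_B^2 psi_B + theta_B +
(lambda_W^2 psi_W + theta_W) / n1)` (`cluster_mean_reliability()`,
`rb_reliability()`; 1.2/1.236 = 0.971 at the default parameters with
`n1 = 50`).  For the corrections themselves the package removes the
contamination subtractively: the corrected between-level latent moments are
the corrected cluster-mean-level moments minus the corrected within-level
moments divided by the (harmonic mean) cluster size — the latent-scale
analogue of the classical ANOVA between-covariance estimator.  For variances
this coincides with multiplying by the latent-level cluster-mean reliability;
for covariances it is exact where a purely multiplicative `R^B` adjustment
cannot be (no per-factor multiplier inverts the contamination once the two
variables' within components are correlated).  Variables observed only at
the cluster level (a between-only moderator) are untouched.  A cross-level
product (`X^W * Z^B`) uses the decontaminated between variance of `Z` inside
the product rule; its covariance with the within-level outcome needs no
`1/n1` term (the contaminating cross-moments are third moments of centered
normals and vanish).

Unbalanced clusters use the harmonic mean cluster size in the `1/n1` terms,
which reduces to `n1` for the balanced designs the generator produces.

## Partially nested designs

The treatment arm gets two-level measurement models for mediator and outcome
and a between-only model for the moderator; the control arm gets single-level
models.  Latent means are fixed to 0 in the control arm; the treatment latent
means (`a(t)` for the mediator, the outcome contrast for the main effect) are
estimated by a pooled GLS mean model with loadings constrained equal across
arms — arm-specific loadings are used for scoring and corrections, but a mean
contrast is only meaningful under some invariance, so the mean model pools.
Three structural models are estimated: treatment-between
(`Y^B ~ M^B + Z + M^B:Z`), treatment-within (`Y^W ~ M^W`), and control
(`Y ~ M`).  Effects: main `= (outcome mean contrast) - B(t) * a(t)` (the
moderator and product scores are centered, so their means drop out),
mediation `= a(t) * B(t)` (exactly the product of its stored factors),
moderation `= xi2(t)`.  The treatment-mediator interaction on the b path
(`B(t) - b1(c)`) is reported descriptively and not folded into the mediation
effect.

Because the moderator has no control-arm counterpart, its latent mean is
identified only up to the treatment-arm centering; the package grand-mean
centers the moderator scores within the treatment arm and notes that the
main-effect recovery relies on this convention.

## What the generator emulates

`generate_mlsem()` draws multivariate normal latent variables with unit
variance per level for exogenous predictors, latent predictor correlation
0.25 at each level, structural slopes 0.4 (first-order) and 0.2
(interaction), conditional outcome residuals 0.8 (within) and 0.2 (between),
and three indicators per factor with unit loadings and residual variances
0.8/0.2 (within/between).  These defaults imply composite reliabilities
0.94 (between) and 0.79 (within):

```{r}
implied_reliability(sam_params())
```

The implied outcome variance decomposition is exposed rather than asserted,
because the generating parameters pin it down only through the model:

```{r}
str(implied_r2(sam_params(), "within"))
```

Under this parameter reading the between level of the within-interaction
design has 66% of outcome variance explained; the within level ~36% with
~3.4% owed to the interaction, and the between-interaction design ~69% with
~6.6% owed to the interaction.  (Reported companion values of "approximately
33%", "72%" and "8%" are not exactly reproducible under any single parameter
reading we tested; the package exposes its own implied quantities instead of
guessing a convention.)

For the partially nested design, the mediator's latent variance decomposes
0.8/0.2 across treatment levels (total 1, matching the control arm's 1.0);
the between-only moderator has unit variance and cluster-level indicators
with residual 0.2; control indicators carry the full residual 1.0.  The
latent interaction is generated from the mediator's between component
centered at its arm mean, so the moderator main effect keeps its stated value
under the centered-product estimation convention.

What the generator does **not** emulate: non-normal latent variables, random
slopes, unbalanced clusters, measurement non-invariance across arms, more
than two levels.  A green simulation test therefore establishes estimator
behaviour under correct specification and normality only.

## Monte Carlo evaluation

`run_condition()` / `run_study()` reproduce the evaluation design: per
condition and estimator they record bias of the interaction coefficient
against the generating value, average absolute bias of all slope coefficients
per level against the *true-model benchmark* (OLS on the exact generated
latent values, `true_empirical_fit()`), the SD of estimates across converged
replications, RMSE `= sqrt(bias^2 + SD^2)`, and convergence-failure rates.
Intercepts are excluded from the averaged metrics (they are 0 by design and,
at the within level, identified only up to the score-centering convention).
Per-replication seeds derive deterministically from the master seed
(`seed * 100003 + i mod 2^31 - 1`), so any single replication can be re-run
in isolation.  Bootstrap inference (`bootstrap_ci()`) resamples clusters with
replacement (arm-stratified for partially nested data; control singletons as
units), re-runs the full pipeline per replicate, and reports 2.5%/97.5%
percentile bounds plus the fraction of non-converged replicates (default
`B = 1000`).

## Numerical choices and degenerate inputs

* Validities or corrected variances below tolerance (`1e-3` / non-positive)
  are declared non-convergence rather than returning exploded estimates.
* A Cauchy–Schwarz violation in the corrected product inputs is
  non-convergence (the corrected matrix cannot be a covariance matrix).
* The predictor block must be PD to machine tolerance; the implied residual
  variance must be non-negative (values above `-1e-8` are clamped to 0).
* Datasets with all-singleton clusters are inestimable at the within level
  and error early; a dataset with zero between variance (identical cluster
  means) yields a non-PD between model and is flagged, including inside the
  bootstrap.

## Known limitations

* Analytic standard errors are out of scope; inference is bootstrap-only.
* The exact correction algebra used by the originating software pipeline for
  between-level components is not published in closed form; this package uses
  the subtractive decontamination validated by its population-consistency
  oracle.  Reproductions of printed Monte Carlo tables are faithful for bias,
  SD, RMSE and the qualitative failure-rate pattern, but the package's
  corrected pipeline is numerically more stable than the original: its
  convergence-failure rates at the smallest cluster counts are lower than
  the printed ones (e.g. ~1-2% versus 8% for the between-level interaction at
  30 clusters of 20), and the residual small-`n1` attenuation the original
  shows for corrected interaction estimates is largely absent.
* Continuous indicators only; no categorical measurement, no global-SAM or
  covariance-only local-SAM variants, no Bayesian estimation.
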