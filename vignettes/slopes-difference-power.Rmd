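---
title: "Probing aptitude-by-treatment-by-time interactions: model, slopes difference test, and Monte Carlo design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing aptitude-by-treatment-by-time interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopediff)
```

## The scientific problem

Precision-education questions — *which* intervention helps *which*
students — are naturally framed as aptitude-by-treatment interactions
(ATI) or skill-by-treatment interactions (STI).  In a longitudinal
cluster-randomized trial (CRT), intact classrooms are assigned to a
treatment or control arm and students are measured repeatedly, so the
interaction of interest is cross-level: classroom-level treatment and
student-level aptitude jointly moderate the student-level relationship
between time and achievement.

The omnibus test of the three-way coefficient says only that *some*
moderation exists.  To answer the precision question one probes the
interaction: the **slopes difference test** asks whether the growth rate
(time slope) of low-aptitude students differs between the treatment and
control arms.  This package implements that test for the three-level
longitudinal mixed model, together with the Monte Carlo machinery needed
to characterize its power and the fitted model's convergence and
singularity behavior across realistic trial designs.

## The three-level model

Occasion $t$ within student $i$ within classroom $j$:

$$
Y_{tij} = \gamma_{000} + \gamma_{001}\,Trt_j + \gamma_{010}\,Apt_{ij}
 + \gamma_{100}\,Time_{tij} + \gamma_{011}\,Trt_j Apt_{ij}
 + \gamma_{101}\,Trt_j Time_{tij} + \gamma_{110}\,Apt_{ij} Time_{tij}
 + \gamma_{111}\,Trt_j Apt_{ij} Time_{tij}
 + u_{00j} + r_{0ij} + r_{1ij} Time_{tij} + e_{tij}
$$

with $u_{00j} \sim N(0, \tau_{\beta00})$ per classroom,
$(r_{0ij}, r_{1ij}) \sim N_2(0, T_\pi)$ per student (free covariance
$\tau_{\pi01}$), and $e_{tij} \sim N(0, \sigma^2)$ per occasion.  The
aptitude-related slopes are fixed across classrooms (they vary only with
treatment), reflecting the common ATI assumption that the
aptitude-achievement relationship does not vary by cluster.  The analysis
model fitted by `fit_lmm()` has exactly this structure; the generative
model in `simulate_dataset()` is the same equation read forwards.

### Parameters and defaults

The condition-independent defaults of `pop_params()` encode a plausible
precision-education scenario on an IQ-like scale:

| parameter | default | meaning |
|---|---|---|
| $\gamma_{000}$ | 0 | grand intercept |
| $\gamma_{001}$ | 0.1 | small treatment main effect |
| $\gamma_{010}$ | 0.5 | strong aptitude-achievement relationship |
| $\gamma_{100}$ | 0.1 | modest average growth per wave |
| $\gamma_{011}$ | 0.3 | treatment effect varies somewhat with aptitude |
| $\gamma_{110}$ | 0.5 | growth depends strongly on aptitude |
| $\gamma_{111}$ | 0.1 | small three-way moderation |
| $\sigma^2$ | 1.0 | occasion residual variance |
| $T_\pi$ | $[0.2, 0.05; 0.05, 0.1]$ | student intercept/slope covariance |
| aptitude | mean 0, SD 15 | centered IQ-like covariate |

Two parameters are design-condition-dependent and therefore have no base
default.  The treatment-by-time coefficient $\gamma_{101}$ carries the
effect size of the slopes difference: labels small/medium/large map to
0.2/0.4/0.6, i.e. slope differences of 0.1/0.3/0.5 at the low-aptitude
conditioning value (since $\gamma_{111} = 0.1$).  The classroom variance
$\tau_{\beta00}$ is set from the intraclass correlation via

$$\tau_{\beta00} = \frac{ICC\,(\sigma^2 + \tau_{\pi00})}{1 - ICC},$$

so ICCs of 0.086, 0.113 and 0.2 give $\tau_{\beta00}$ of 0.113, 0.153
and 0.3 (the first two to three decimals; full precision is carried
internally).  `resolve_params()` performs exactly these two
substitutions.

One acknowledged tension in this parameterization: the outcome is
described as living on an SD-15 scale, but the generative equation with
an SD-15 aptitude and the coefficients above determines the realized
outcome scale by itself (aptitude terms dominate the outcome variance).
The generator implements the equation as written and does not rescale
the outcome.

### Design conditions

`build_grid()` crosses 3 wave counts (3/4/5) x 3 class sizes
(10/20/30) x 4 classroom counts (20/30/40/50) x 2 treatment proportions
(0.5/0.3) x 3 ICCs x 3 effect sizes = 648 conditions.  Waves are coded
centered with unit spacing (`wave_times()`), e.g. $(-1, 0, 1)$ for three
waves.  The enumeration order is documented (waves outermost, effect
size innermost) so that `condition_index` is reproducible; because the
original report never states its own ordering, specific published
conditions are identified by their factor values, never by index.
Treated-classroom counts are deterministic (`round(pJ)`, half-up); only
which classrooms are treated is random.  Every published $(J, p)$ pair
gives an integer count, so this choice loses nothing and makes power
attribution cleaner.

## The slopes difference test

At aptitude $a$, the treatment-minus-control difference in time slopes
is $\gamma_{101} + a\,\gamma_{111}$.  "Low aptitude" is conditioned at
$a = -1$ in raw units — deliberately so, matching the published
formulation, even though aptitude has SD 15; the value is configurable.

`slopes_difference_test()` offers two variance conventions:

* **`as_printed`** (default): $t = (\hat\gamma_{101} - \hat\gamma_{111})
  \big/ \sqrt{\widehat{var}(\hat\gamma_{101}) +
  \widehat{var}(\hat\gamma_{111}) +
  2\,\widehat{cov}(\hat\gamma_{101},\hat\gamma_{111})}$, exactly as the
  test is printed in the literature this package follows.
* **`delta_method`**: the general conditional-contrast variance
  $var(\hat\gamma_{101}) + a^2 var(\hat\gamma_{111}) +
  2a\,cov(\hat\gamma_{101},\hat\gamma_{111})$, which at $a=-1$ carries
  the covariance with the *opposite* sign.

The two coincide exactly when the covariance is zero, and with a
centered aptitude distribution the estimated covariance is very nearly
zero, so the distinction is numerically minor here.  Both are exposed
because the printed "+2cov" disagrees with the textbook conditional
variance and we refuse to guess which one any particular historical
analysis ran.

The reference distribution is standard normal by default (`df_policy =
"normal"`).  A `"residual"` policy ($df = N - p - 1$, the single-level
regression convention) is provided; at the smallest simulated size (600
occasions, $df = 591$) the two differ negligibly.  Significance is
declared two-sided at $\alpha = 0.05$ by default.

```{r probe-example}
cond <- build_grid()[7, ]   # 3 waves, 10/class, 20 classrooms, ICC 0.2, small
d <- simulate_dataset(cond, stream = seed_stream(1, 7, 1))
f <- fit_lmm(d)
slopes_difference_test(f)
```

## Estimation, convergence and singularity

`fit_lmm()` delegates REML estimation to `lme4::lmer()`, which expresses
the exact random-effects structure, profiles out the residual variance,
and optimizes over the Cholesky factor of the scaled covariance matrices
— so boundary fits are returned rather than erroring, which is what
makes the singular-vs-nonconverged distinction meaningful.

* **Convergence** (package criterion, configurable `grad_tol`): the
  optimizer must report success *and* the Newton-scaled gradient
  $\max|H^{-1}g|$ of the profiled objective must be at most `2e-3`, the
  convention of the mixed-model software family this package targets.  A
  raw (unscaled) gradient threshold was rejected during design: the
  gradient components live on very different scales across the
  variance parameters, and an unscaled cutoff misclassifies fits whose
  scaled gradient is tiny.
* **Singularity** (`is_singular_fit()`, tolerance `1e-4`): any
  random-effect SD at zero relative to the residual scale, a zero
  conditional slope SD, or $|\hat\rho| \ge 1 -$ tol for the student
  intercept-slope correlation — equivalently a zero diagonal in the
  scaled Cholesky factor the optimizer works on.  Singular fits still
  yield a test statistic; they count toward power and toward the
  singularity rate independently.

Reported convergence and singularity *rates* are therefore
criterion-dependent; the defaults above are the package's documented
choices, not universal constants.

**Degenerate inputs.** If the outcome is an exact linear function of the
fixed part (all generating variances zero), the mixed-model likelihood
is flat in directions where fixed effects are confounded with random
effects and GLS coefficients are not unique.  `fit_lmm()` detects exact
interpolation (relative residual sum of squares below `1e-10`) and
returns the unique ordinary-least-squares solution with all variance
components at the boundary, flagged singular.

The REML criterion reported by `fit_lmm()` is validated in the test
suite against an independent dense-matrix evaluation of the closed-form
restricted log-likelihood, and against a generic optimizer run over that
oracle (no better optimum is found).

## The Monte Carlo engine

`run_condition()` replicates simulate -> fit -> probe and aggregates:

* **power** — share of significant slopes difference tests.  The default
  denominator is *all* replications (failed or non-converged replications
  count as non-significant); a converged-only denominator is also
  reported, because the original description ("across all replications")
  does not settle the question.  With convergence rates near 0.999 the
  two are numerically indistinguishable, but the policy is explicit.
* **convergence rate**, **singularity rate** — shares over all
  replications.
* **accuracy** — mean fixed-effect estimates across converged fits and
  their relative bias against the generating values.

Reproducibility is hierarchical: replication $r$ of condition $c$ under
master seed $m$ uses the L'Ecuyer-CMRG stream reached by $c$
`nextRNGStream` steps and $r$ `nextRNGSubStream` steps from $m$
(`seed_stream()`).  Streams are independent of scheduling, so
`run_grid()` produces bitwise-identical tables serially or with forked
workers, and interrupted runs resume from a per-condition CSV checkpoint
(a checkpoint with mismatched settings is refused).  Within one dataset,
draws consume the stream in a fixed order: treatment assignment,
classroom effects, aptitudes, student effects, residuals.

The aptitude distribution is Normal; the reference description states
only mean 0 and SD 15, and Normal is the conventional reading of a
"centered IQ" scale.  Replications are fully independent — aptitude is
redrawn per dataset.

## Meta-analysis of simulation outcomes

The unit of analysis is the *condition* (one row per design cell),
matching the degrees of freedom of the reference report; per-replication
outcomes are never fed to these ANOVAs.  `anova_eta2()` decomposes a
condition-level outcome over the design factors (all categorical) with
$\eta^2 = SS_{term}/SS_{total}$ — two-way interactions included for
power, main effects only for convergence and singularity.  Inputs must
form a complete balanced factorial (sequential sums of squares then
coincide with every other type); unbalanced tables are rejected rather
than silently reweighted.  `tukey_hsd()` runs studentized-range post-hoc
comparisons using the residual mean square of the main-effects ANOVA,
gated in `cmd_analyze()` at $\eta^2 > 0.03$.  `threshold_percentages()`
tabulates, e.g., the share of underpowered conditions (power < 0.8) by
design slice; empty slices are reported missing, not zero.

## Problem sizes used by the test suite

The package's checks run at sizes chosen to exercise every claim while
remaining routine on a single desk machine:

* The two headline single conditions (lowest power; highest singularity
  rate) are verified at the full 1000 replications.
* The full 648-condition grid is verified at 5 replications per
  condition.  Grid *means* (mean power, mean convergence, mean
  singularity) are unbiased at any replication count, so 5 replications
  estimate them with Monte Carlo SE below 0.009; the $\eta^2$ for effect
  size is checked after subtracting the binomial measurement noise that
  few-replication power estimates add to every sum of squares
  ($E[SS_{term}] = SS_{true} + df_{term}\bar v$).  Quantities that are
  *not* identifiable from few replications per condition — notably the
  share of individual conditions above a power threshold, which is
  biased when each condition's power estimate is coarse — are exercised
  on constructed tables instead and reproduced faithfully only by a
  full-scale run.
* Type-I calibration of the probe ($\gamma_{101} = \gamma_{111}$, so the
  true slope difference is zero) uses 1000 replications.

A full-scale rerun of the reference design (648 conditions x 1000
replications, about 648,000 REML fits) is a `run_grid()` call away and
takes on the order of a day on one core; the checkpoint and worker
options exist for exactly that use.

## Known limitations

* Balanced panels only: no missing data, dropout, or varying cluster
  sizes within a run; two arms only; equally spaced waves.
* Gaussian everything: non-Normal residuals or aptitudes, and
  measurement error in aptitude, are out of scope.
* No classroom-level random slopes (by design, mirroring the ATI
  assumption), no crossed random effects, no small-sample covariance
  corrections (Kenward-Roger) and no Johnson-Neyman regions.
* Passing simulation checks speak to this generative model; real data
  with unmodeled heterogeneity (unbalanced clusters, floor effects,
  informative dropout) can behave differently, and the power surface
  mapped here should be read as a best case.
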