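---
title: "Robust interrupted time series models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust interrupted time series models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robits)
```

## The problem

An interrupted time series (ITS) design measures an outcome repeatedly
before and after an intervention — a new hospital policy, a public-health
regulation — and asks what the intervention changed.  Classical segmented
regression fixes the boundary between the two regimes at the formal
intervention date.  In practice interventions rarely bite on their start
date: learning effects delay the change, anticipation moves it earlier.
Fixing the change-point at the wrong place biases every downstream effect
estimate.  A second gap in classical practice is that an intervention can
change more than the mean: an intervention aimed at making an outcome more
*predictable* may leave the mean level untouched while reducing the
variance and increasing the autocorrelation of the series.

`robits` addresses both gaps.  The change-point is *estimated* from the
data over a user-specified candidate window anchored at the formal
intervention time, and the error process is allowed phase-specific
variance and correlation parameters.  With several units (hospitals,
clinics, sites) measured on the same grid, the units share one global
change-point — pooling information across units sharpens its estimate —
while every other parameter stays unit-specific.

## The model

For unit $i$ at tick $t = 1, \dots, n$ the outcome decomposes as
$y_{it} = \mu_{it} + \epsilon_{it}$, with a piecewise-linear mean

$$
\mu_{it} =
\begin{cases}
\beta_{i0} + \beta_{i1}\,t, & t < \tau\\
(\beta_{i0} + \delta_i) + (\beta_{i1} + \Delta_i)\,t, & t \ge \tau
\end{cases}
$$

where $\tau$ is the change-point, defined throughout as the **first index
of the post-change regime**.  $\delta_i = \Delta_i = 0$ means "no change
in unit $i$'s mean function".  The two headline effect measures are

* **level change** $\delta_i + \Delta_i \tau$ — the discontinuity between
  the pre-phase mean projected to $\tau$ and the post-phase mean there
  (the change in the intercept *anchored at the change-point*); and
* **trend change** $\Delta_i$ — the change in slope.

Residuals $r_{it} = y_{it} - \hat\mu_{it}$ follow a phase-specific AR(1)
by default:

$$
r_{it} = \begin{cases}
\phi_{i1} r_{i,t-1} + e_{it,1}, & 1 < t \le \tau - 1\\
\phi_{i2} r_{i,t-1} + e_{it,2}, & \tau - 1 < t \le n
\end{cases}
\qquad e_{it,j} \sim N(0, \sigma^2_{iw,j}),
$$

so the marginal variance in phase $j$ is $\sigma^2_{iw,j} / (1 -
\phi_{ij}^2)$.  We take the phase boundary literally: the innovation at
$t = \tau$ already uses the post-phase parameters and regresses on
$r_{i,\tau-1}$ across the boundary.  Alongside the mean changes, the fit
reports the change in adjacent correlation $\phi_{i2} - \phi_{i1}$ and
the change in marginal variance.

Two further error structures are available.  **Independent** errors fix
$\phi = 0$ with phase-specific variances.  The **exchangeable** structure
is our compound-symmetry reading of a constant within-phase pairwise
correlation: the method's literature names this option without printing
equations, so we model phase $j$ as $\mathrm{Cov}(r_t, r_s) = \sigma_j^2
[\mathbf{1}(t = s) + \rho_j \mathbf{1}(t \ne s)]$ within the phase, with
the phase variance itself as the marginal variance, the average
off-diagonal product moment as the moment estimator of $\rho_j$, and the
closed-form inverse square root of the compound-symmetry block as the
whitening transform.  This is a design choice, flagged here because it is
an interpretation rather than a transcription.

## Estimation

All parameters are estimated jointly by profiling over the candidate set
$Q$:

1. **Per candidate $\tau = q$**, each unit is fitted by iteratively
   re-weighted least squares: generalized least squares (GLS) for the
   four mean parameters under the current whitening transform, then
   method-of-moments (MoM) updates of the noise parameters from the
   residuals, alternating from an ordinary-least-squares start
   ($\phi = 0$) until the largest absolute parameter change falls below
   `tol = 1e-8` or `max_iter = 50` iterations (non-convergence returns
   the last iterate with a warning and a flag).
2. **The change-point estimate** $\hat\tau$ is the candidate maximizing
   the summed conditional log-likelihood of the innovations,
   conditioning on each unit's first observation (ties break to the
   earliest candidate; a candidate whose fit fails, e.g. by rank
   deficiency, is dropped with a warning).  Setting
   `rits_control(condition_on_first = FALSE)` adds the stationary
   marginal density of the first observation.
3. **Final estimates** are the IRLS fits at $\hat\tau$.

The whitening transform maps residuals to unit-variance innovations: row
1 scales by the inverse pre-phase marginal standard deviation, row $t \ge
2$ computes $(r_t - \phi_{j(t)} r_{t-1}) / \sigma_{w,j(t)}$.  Its Gram
matrix is the inverse error covariance, so the GLS coefficient covariance
is simply $(X^\top L^\top L X)^{-1}$.

### Small-sample corrections in the moment estimates

Two corrections matter at realistic phase lengths (tens of points) and
are applied always:

* the phase residual variance uses the divisor $m - 2$, accounting for
  the intercept and slope absorbed per phase;
* the lag-1 autocorrelation is corrected for its well-known negative
  small-sample bias.  For mean-detrended series the classic first-order
  correction is $(1 + 3\phi)/m$; for residuals of an intercept-plus-trend
  fit the bias is about twice that (we verified the factor by simulation
  across $\phi \in \{0, 0.3, 0.6\}$ and $m \in \{25, 50, 100\}$), so we
  use $\hat\phi + 2(1 + 3\hat\phi)/m$, clamped to $[-0.99, 0.99]$.

Without these corrections the Wald test below rejects a true null about
three times too often at $n = 100$.

### Uncertainty reporting

Confidence intervals and p-values for the phase estimates and the change
summaries are Wald-type with standard-normal quantiles from the GLS
covariance, **conditional on $\hat\tau$** — uncertainty in the
change-point itself is not propagated, a deliberate and documented
limitation shared with the conditional reporting convention of this model
family.  The variance of the adjacent-correlation change uses the
asymptotic variance $(1 - \phi^2)/m$ of the lag-1 autocorrelation per
phase (reported as descriptive, and absent, for the exchangeable and
independent structures).  The variance-change interval uses the
normal-theory approximation $\mathrm{Var}(\hat v_j) \approx 2 v_j^2 /
(m_j - 1)$ and should be read as descriptive under autocorrelation.

## The supremum Wald test

Existence of a change-point anywhere in the panel is tested formally.
For each candidate $q \in Q$, stack the per-unit change estimates
$(\hat\delta_i, \hat\Delta_i)$ — selected by a contrast matrix $C$ from
the $4N$-vector of alternative-model estimates — and form

$$
W_q = (C\hat\beta)^\top \left[ C \widehat V C^\top \right]^{-1}
      (C\hat\beta) \;\sim\; \chi^2_{2N} \text{ under } H_0,
$$

with $\widehat V$ block-diagonal across units (units independent).  The
$|Q|$ p-values are Benjamini–Hochberg adjusted, and a change-point is
declared to exist for at least one unit if any adjusted p-value falls
below $\alpha$.  Each unit is additionally labelled "effective
change-point" or "no change-point" from a unit-level 2-df Wald test at
$\hat\tau$, BH-adjusted across units — the unit-level test is our reading
of how per-unit labels should be produced; the literature states only the
p < 0.05 labelling rule.

**Which covariance goes into the quadratic form?**  The textbook Wald
test uses the covariance of the *alternative* estimator.  Here the
alternative covariance rests on phase-specific noise parameters estimated
from half-length segments, and its plug-in noise makes the test
noticeably anti-conservative: at $N = 4$, $n = 100$, $\phi = 0.3$,
$|Q| = 11$ we measured a type-I error around 0.095 instead of 0.05 (500
replicates).  Evaluating the GLS covariance of the segmented-design
estimator under the *null-fitted single-phase* noise — the natural
plug-in when the hypothesis under test is "no change", and the
formulation this model family's test statistic actually writes down —
brings the empirical size to about 0.034, inside the 95% binomial band
around the nominal level.  `rits_control(wald_cov = "null")` is therefore
the default; `"alt"` remains available.  The residual conservatism is the
usual price of plug-in noise parameters; a variant that also *estimates*
the mean under null whitening is per-component calibrated but jointly
over-conservative because $\hat\delta$ and $\hat\Delta$ are nearly
collinear, and was rejected.

The null model itself (intercept + slope, one noise phase per unit) is
fitted with the same IRLS machinery; its correlation structure is the
single-phase version of whatever family the alternative uses.

## Synthetic data

`rits_scenario()` / `simulate_its()` draw datasets with *exactly* the
model's stochastic structure: the first residual comes from the pre-phase
stationary marginal distribution (which makes closed-form moment checks
exact), subsequent residuals follow the phase-switching recursion above,
and units are independent.  `rits_preset()` bundles the canonical study
conditions used throughout the tests:

| preset | N | n | what it emulates |
|---|---|---|---|
| `null` | 4 | 100 | no change anywhere; AR(1) $\phi = 0.3$, $\sigma^2_w = 1$ |
| `level-jump` | 1 | 100 | a 5-marginal-SD jump at $\tau = n/2$ |
| `slope-change` | 1 | 100 | slope bends by 0.05 per tick |
| `noise-only-change` | 4 | 100 | mean unchanged; $\phi$ 0.2→0.6, $\sigma^2_w$ 1→0.5 |
| `paper-shape` | 4 | 193 | biweekly multi-year panel (2010-01-01 onward) |

The `noise-only-change` preset is the motivating case for phase-specific
noise: the mean test has nothing to find, but the fitted
adjacent-correlation change is nonzero.  The generator emulates the
model, not real data: real patient-experience series have seasonality,
heavier tails, floor/ceiling effects and missingness patterns none of
which are drawn here — passing tests certify the estimator under its own
assumptions, not robustness to their violation.

## Data ingestion rules

* CSV/TSV, wide layout: one time column, one numeric column per unit;
  ISO dates, a user-supplied format string, or plain integer ticks.
* The grid must be evenly spaced up to a modal-step tolerance.  The
  default tolerance is 15% relative to the modal step — *not* tighter —
  because calendar-month grids step 28–31 days and monthly panels are the
  method's canonical use case.  Genuinely irregular sampling is rejected.
* Units are restricted to their overlapping time points (a unit observed
  only through 2015 truncates every other unit to 2015).
* Interior missing cells are linearly interpolated *on the calendar
  axis*, with a warning listing the imputed positions: interpolation
  biases noise-parameter estimates toward smoothness, and series with
  much missingness should not be analysed this way.  Edge missing values
  cannot be interpolated and are trimmed with a warning.
* Candidate change-points are the measurement dates inside a
  user-chosen window, filtered to leave at least `min_segment = 4`
  observations per phase (two points for the line, two residual pairs
  for the noise parameters).

## Numerical and testing conventions

* Internal analysis runs on 1-based integer ticks; all date↔index
  mapping happens at the ingestion boundary.
* IRLS: OLS start, `tol = 1e-8` on the maximum absolute parameter
  change, `max_iter = 50`.
* Likelihood ties across candidates break to the earliest candidate.
* Simulation-based checks in the test suite compare empirical rejection
  rates against binomial bands, use common random numbers across effect
  sizes when asserting power monotonicity (with a fixed 0.05 Monte-Carlo
  slack), and compare simulation biases with a two-standard-error
  Monte-Carlo allowance — at a few hundred replicates the bias of an
  unbiased estimator is a Monte-Carlo zero, and a strict comparison of
  two such zeros would be a coin toss.  Problem sizes used by the
  heavier checks: 500 replicates for test size, 2000 for the
  $\chi^2_{2N}$ reference, 200 for change-point and parameter recovery,
  100 per effect size for power.

## A worked example

```{r example}
sc <- rits_preset("level-jump", N = 2, n = 100)
d <- simulate_its(sc, seed = 42)
fit <- rits(d, candidates = 40:60)
fit

st <- supremum_wald_test(d, 40:60)
st$exists
```

## Known limitations

* One global change-point across units; unit-specific change-points are
  out of scope.
* No covariates, no discrete outcomes, no AR(p > 1) or MA(q) noise.
* Confidence intervals condition on the estimated change-point.
* The exchangeable structure is an interpretation (see above), and its
  correlation-change uncertainty is not quantified.
* Linear interpolation of missing values biases dependence estimates;
  prefer complete series.
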