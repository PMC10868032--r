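---
title: "Methods: flagging biologically implausible values in longitudinal child growth data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flagging biologically implausible values in longitudinal child growth data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivclean)
```

Routine growth-monitoring systems accumulate length/height and weight
records for children under five that are contaminated by digitization
errors: decimal shifts, unit mistakes, transposed digits, swapped fields,
duplicated rows, and values carried over from other children. Left in
place, these biologically implausible values (BIVs) distort estimates of
stunting and underweight prevalence. `bivclean` implements a staged,
fully accounted cleaning pipeline that combines three complementary
detectors:

1. **Population outliers (PO):** measurements extreme relative to an
   external growth reference, via LMS z-scores.
2. **Longitudinal outliers (LO):** measurements extreme relative to the
   child's *own* modelled trajectory, via scaled residuals from a
   random-intercept mixed model.
3. **Decreasing heights:** stature losses exceeding 2 cm between visits,
   which are biologically impossible in this age range.

This vignette documents the statistical model, the parameter choices, the
synthetic-data generator, and the numerical decisions, in that order.

## LMS z-scores and population outliers

A growth reference supplies, for each indicator (HAZ, WAZ, BMIZ, WHZ), sex
and age (or length, for WHZ), the Box–Cox power `L`, median `M` and
coefficient of variation `S`. The z-score of a measurement `y` is

$$ z = \frac{(y/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
   z = \frac{\log(y/M)}{S} \quad (L = 0), $$

with the inverse `y = M (1 + L S z)^{1/L}`. `L`, `M`, `S` are linearly
interpolated between tabulated ages. Following WHO practice, extreme
z-scores for the weight-based indicators (WAZ, BMIZ, WHZ) are adjusted in
the tails: beyond |z| = 3 the score is recomputed as 3 plus the distance
from the ±3 centile in units of the local centile gap, which stabilizes
scores where the Box–Cox tail is unreliable. HAZ is never adjusted, and
the adjustment is the identity when `L = 1`.

A record is a population outlier when its z-score falls strictly outside
fixed cutoffs: HAZ (−6, +6), WAZ (−6, +5), BMIZ (−5, +5), WHZ (−5, +5).
By default the height stream is screened on HAZ and the weight stream on
WAZ (`po_dataset_kind = "per_stream"`); a combined mode screens on all
indicators at once.

## Pipeline stages and accounting

Each measurement stream (height, weight) passes through, in order: exact
duplicate removal (keyed on child, birth date, visit date, and both
measurements), removal of missing/non-positive values and visits outside
0–59 months, removal of children with a single remaining visit, PO
removal, a second singleton pass (PO removal can orphan a child's last
companion visit), model fitting, and LO flagging at cutoffs 3–6 in
parallel branches. The height stream adds the decreasing-heights branch.
Every stage emits `records_in = records_removed + records_kept`, stages
chain exactly, and every removed record carries at least one flag; these
invariants are asserted in the test suite on every pipeline run. The
prevalence report recomputes HAZ/WAZ category shares at each stage, with
the initial table carrying explicit BIV and Missing rows so denominators
are always the full record count.

## The longitudinal model

For child $i$ at visit $j$ with age $t_{ij}$ (computed as days/30.4375):

$$ y_{ij} = x(t_{ij})^\top \beta + b_i + \varepsilon_{ij}, \qquad
   b_i \sim N(0, \tau^2), \quad \varepsilon_{ij} \sim N(0, \sigma^2), $$

where $x(t)$ is a restricted cubic spline basis in age: a linear column
plus $K-2$ truncated-cubic combinations constrained to be linear beyond
the boundary knots (C2-continuous everywhere). Knots are placed at ages
{2, 6, 12, 24, 58} months for height and {3, 6, 12, 58} for weight,
concentrating flexibility where growth velocity changes fastest. Models
are fit separately by sex and by measure.

Estimation profiles the variance ratio $\lambda = \tau^2/\sigma^2$:
for fixed $\lambda$, $\beta$ and $\sigma^2$ have closed forms through the
rank-one identity $(I + \lambda 1 1^\top)^{-1} = I - c\,11^\top$ with
$c = \lambda/(1 + \lambda J_i)$, so one likelihood evaluation costs
$O(Np + np^2)$ and the full fit is linear in the number of observations.
$\lambda$ is maximized on the log scale by a 61-point grid over
$[10^{-10}, 10^6]$ followed by Brent's method, with REML (default) or ML
objectives. $\tau^2$ may hit the zero boundary, which is reported
explicitly.

### Scaled residuals and LO flags

The default flagging residual is the **marginal** scaled residual

$$ R_{ij} = \frac{y_{ij} - x(t_{ij})^\top \hat\beta}
                 {\sqrt{\hat\sigma^2 + \hat\tau^2}}, $$

i.e. the observed deviation scaled by the estimated standard deviation of
$Y_{ij}$. Under a correctly specified model these residuals have mean 0
and spread 1, so the expected flag rate at cutoff $k$ is
$2\Phi(-k)$ — about 0.27% at $k = 3$.

A **conditional** mode subtracts the BLUP
$\hat b_i = \frac{J_i\hat\tau^2}{\hat\sigma^2 + J_i\hat\tau^2}\bar r_i$
and scales by $\hat\sigma$. BLUP shrinkage makes conditional residuals
*under*-dispersed: their variance is
$\sigma^2\big[1 - 2c + c^2 J + \lambda/(1+\lambda J)^2 \sigma^{-2}\tau^2\big]$-style
rather than $\sigma^2$, and at values of $\lambda$ typical for child
growth (between-child variation several times the visit-level noise, e.g.
$\tau = 2$ cm, $\sigma = 0.8$ cm, $J \approx 4$) the conditional residual
has spread ≈ 0.87 and a ±3 exceedance rate near 0.06%. The marginal form
is therefore the default — it is the definition whose null behaviour
matches the nominal $2\Phi(-k)$ rate — while the conditional form remains
available for isolating visit-level (as opposed to child-level) anomalies
when shrinkage is accounted for. The shrinkage algebra only becomes
negligible when $\lambda J \ll 1$:

```{r null-rate}
d <- simulate_lmm_data(4000, 4, tau = sqrt(0.1), sigma = 1, seed = 5)
fit <- fit_random_intercept_lmm(d$X, d$y, d$subject)
round(100 * c(
  marginal    = mean(abs(scaled_residuals(fit, mode = "marginal")) > 3),
  conditional = mean(abs(scaled_residuals(fit, mode = "conditional")) > 3)
), 3)
```

Internally and externally studentized variants divide by
$\sqrt{(\hat\sigma^2+\hat\tau^2)(1 - h_{ij})}$ with leverage
$h_{ij} = \sigma^2 x^\top (X^\top V^{-1} X)^{-1} x / (\sigma^2+\tau^2)$;
the external form applies the exact leave-one-out identity
$t = r\sqrt{(\nu-1)/(\nu-r^2)}$. Both are capped at dataset sizes where
their $O(Np^2)$/$O(N)$ refit costs stay interactive; at pipeline scale the
leverage correction is negligible and the plain scaled residual is used.

An observation is an LO at cutoff $k$ when $|R_{ij}| > k$ strictly.
Cutoffs 3, 4, 5 and 6 are evaluated as parallel branches against the same
post-PO data, so flag sets nest by construction
($k=6 \subseteq 5 \subseteq 4 \subseteq 3$).

### Decreasing heights

Within a child, visits are scanned in age order keeping a running
last-accepted height; a value more than 2 cm *below* the last accepted
value is flagged, and flagged values do not update the running reference
(so a single corrupt visit does not cascade into flagging the recovery).
`[60.0, 57.5, 61.0]` flags only the middle value; `[50.0, 49.1]` flags
nothing.

## Synthetic data generator

`simulate_children()` draws per-child sex, birth date, 2–8 visits with
first visit uniform in 0–12 months and gaps of 1–10 months, and generates
height and weight as median curve + child intercept
($\tau_\text{height}=2$ cm, $\tau_\text{weight}=0.5$ kg) + visit noise
($\sigma_\text{height}=0.8$ cm, $\sigma_\text{weight}=0.25$ kg), rounded
to 0.1 cm / 0.01 kg as field instruments do. The built-in toy reference
(`make_toy_reference()`) uses fixed `S` values (0.035 length, 0.11
weight, 0.09 BMI) with `L = 1`, and sex offsets of ±0.6 cm / ±0.25 kg.

The toy median curves are deliberately **restricted-cubic-spline
functions on the default knots** with frozen coefficients, rather than an
arbitrary smooth curve. The generator and the cleaning model must agree
on the mean structure for the package's own consistency checks to be
meaningful: a median curve outside the spline span leaves systematic
lack-of-fit that inflates $\hat\sigma^2$ (a quadratic alternative we
evaluated leaves ≈ 0.4 cm RMS lack-of-fit, biasing $\hat\sigma^2$ upward
by roughly 25%) and breaks variance-recovery invariants. The frozen
coefficients anchor median length at 50 cm and weight at 3.3 kg at birth
and are verified strictly increasing over 0–59 months.

```{r recovery}
sim <- simulate_children(sim_config(n_children = 1500, seed = 21))
r <- sim$records
r$age <- compute_age_months(r$birth_date, r$visit_date)
# one sex, as the pipeline fits: pooling would add the sex-offset variance
rM <- r[r$sex == "M", ]
fit <- fit_growth_lmm(rM$age, rM$length_height_cm, rM$child_id)
c(tau2 = fit$tau2, sigma2 = fit$sigma2)   # truth: 4 and 0.64
```

`inject_errors()` corrupts a labelled fraction of records with decimal
shifts, metre-for-centimetre unit errors, digit transpositions,
height/weight swaps, exact duplicate rows, missing fields and implausible
height decreases (3–10 cm below the child's previous visit, so every
injected drop violates the −2 cm rule). Targets are disjoint — each
original record carries at most one error, and duplicates copy untargeted
rows — and `evaluate_flags()` scores any flag set against the truth
labels by error type and flag family.

**Realism and limits.** The generator reproduces the features the
detectors key on (within-child correlation, visit spacing, rounding, the
error taxonomy) but not everything in field data: no secular trends, no
measurement error that grows with age, no informative visit timing, no
device-specific digit preference, and a single random intercept rather
than child-specific growth *rates*. Benchmark sensitivities on it are
upper bounds for field performance.

## Numerical choices

- **Generalized RSS from explicit residuals.** The profiled likelihood
  computes $e^\top V^{-1} e$ as
  $e^\top e - \sum_i c_i (\sum_j e_{ij})^2$ with $e = y - X\beta$,
  not from the sufficient-statistic form $y^\top y - \ldots$; the latter
  cancels the large $y^\top y$ scale and the lost digits measurably bias
  the position of the flat profile maximum.
- **Profile search.** Log-scale grid (61 points over $[10^{-10},10^6]$)
  + Brent, then a parabolic polish with shrinking spacing
  ($10^{-3}, 10^{-4}, 2\times10^{-5}$ in $\log\lambda$): Brent stops when
  objective differences hit evaluation noise, and the polish recovers
  several further digits of $\hat\lambda$ on flat maxima (validated
  against the closed-form balanced one-way ANOVA identity to $\sim10^{-8}$).
- **Stability guards.** Rank checks on a column-normalized design
  (raw spline columns reach $10^5$ and would defeat a raw `qr` tolerance);
  `log1p` for $\log|V|$; Cholesky solves throughout; strict inequalities
  at all flag cutoffs so boundary values are never flagged.
- **Determinism.** The generator splits its seed into independent
  substreams per component, and the pipeline is a pure function of its
  inputs: reruns are byte-identical, which the acceptance suite asserts
  on serialized outputs.
- **Problem sizes.** The test-suite instance sizes (e.g. 5 subjects / 20
  observations for the dense oracle, 2,000 children for recovery, 50,000
  measurements for the null flag rate) are this package's own choices,
  sized so each property is sharp at desk scale.

## Limitations

- The trajectory model has a random intercept only; children with
  atypical growth *velocity* can generate legitimate measurements with
  large marginal residuals. Cutoffs of 3–6 SD keep such false flags rare
  (the clean-data false-flag rate is asserted ≤ 1% in the benchmark), but
  LO flags should be read as "implausible given a common growth shape".
- PO detection is only as good as the supplied reference; the bundled toy
  reference is for testing and simulation, not clinical use.
- Duplicate detection keys on exact field equality and will not catch
  near-duplicates (same visit re-entered with a typo).
- The decreasing-heights rule assumes visits can be ordered by age;
  unordered input is an error rather than silently mis-scanned.
- Serial correlation beyond the shared intercept (e.g. measurement
  campaigns) is not modelled and would inflate the apparent visit-level
  variance.
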