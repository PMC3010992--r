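---
title: "Estimating navigation ability from satellite tracks: the circle-of-confusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating navigation ability from satellite tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocnav)
```

## The question and the model

A migrating animal that navigates by indirect cues (geomagnetic field,
olfaction, currents) cannot know its position exactly. Its *circle of
confusion* is the radius around its true position within which it cannot
resolve its location; the larger the circle, the poorer the navigation
ability. `cocnav` estimates this radius for a collection of
satellite-tracked animals under one minimal assumption: each animal intends
to follow the most direct route — the great circle — from its migration
start point to its destination.

The observable is the sequence of signed perpendicular great-circle
distances (cross-track deviations, km) of the animal's daily positions from
its route, positive to the left of the direction of travel. Deviations are
signed because an animal on one side of the route tends to remain on that
side; an unsigned series would destroy exactly the autocorrelation the
model measures. Writing \(y_t\) for the observed deviation on day \(t\) and
\(x_t\) for the latent true deviation,

\[
y_t = x_t + \varepsilon_t, \qquad \varepsilon_t \sim N(0, \sigma_\varepsilon^2),
\]
\[
x_t = \gamma_j x_{t-1} + w_t, \qquad w_t \sim \sigma_j \, t_\nu,
\]

an AR(1) state-space model with Gaussian measurement error and scaled-t
process error. The heavy-tailed \(t_\nu\) shock keeps the estimates from
being inflated by transient forced deviations — foraging detours,
deflection by currents — that are not navigation failures; fitted degrees
of freedom near 2–4 are typical and confirm that the robustness matters.

The circle of confusion is the stationary scale of the deviation process,

\[
\mathrm{CoC}_j = \frac{\sigma_j}{\sqrt{1 - \gamma_j^2}},
\]

computed from the **scale** \(\sigma_j\) of the t shock, not its standard
deviation. This matters: the fitted \(\nu\) routinely approaches or dips
below 2, where the t variance is infinite, so a variance-based definition
would be undefined exactly in the regime the model inhabits.
`coc_radius(..., corrected = TRUE)` provides the variance-corrected radius
\(\sqrt{\nu/(\nu-2)}\,\sigma_j/\sqrt{1-\gamma_j^2}\) when \(\nu > 2\) for
users who want it. Multiplying a CoC by `coc_interval()`'s default 1.96
converts it to the 95% confidence radius of where the animal believes it
is.

Both a large \(\sigma_j\) (noisy corrections) and a \(\gamma_j\) near 1
(failure to correct back toward the route) inflate the circle; high
autocorrelation with small shocks and small autocorrelation with large
shocks can produce the same radius, and the posterior reflects that ridge.

## Hierarchical structure

Individual parameters are drawn from population distributions:
\((1+\gamma_j)/2 \sim \mathrm{Beta}(a, b)\) (keeping \(\gamma_j\) in
\((-1,1)\)) and \(\sigma_j \sim N(\theta, \tau^2)\) truncated to
\((0,\infty)\). Pooling across animals stabilizes the poorly identified
individual stationary scales, and the fitted hyper-parameters define the
*predictive distribution* — the package's estimate of the navigation
ability of an unobserved individual from the same population
(`predictive_coc()`, the starred rows of `summary()`).

Under `grouping = "by_sex"` every hyper-parameter (including \(\nu\)) is
duplicated per sex; the measurement error is common to all animals in
either grouping, because it is a property of the tag-and-regularization
system rather than of the animal.

### Priors and their bounds

* \(\sigma_\varepsilon \sim N(2\ \mathrm{km}, 0.02\ \mathrm{km})\)
  truncated at 0 — an informative prior. Published per-class Argos error
  magnitudes average about 2 km, and the daily robust regularization
  removes most of the raw scatter; the prior pins what a single series
  cannot identify (measurement vs process noise at the daily scale). It is
  a `coc_priors()` argument, so sensitivity analysis is one line.
* \(a \sim U(1, 150)\), \(b \sim U(0.3, 20)\). Two failure modes dictate
  these bounds, and both were observed in simulation during development.
  If \(a\) is capped low (say 20 with \(b \ge 1\)), the population mean of
  \(\gamma\) cannot exceed \(\approx 0.9\), and every individual in the
  realistic 0.97–0.99 regime is dragged down. If \(a\) is effectively
  unbounded, the opposite happens: each \(\gamma_j\) likelihood is flat
  along a ridge toward 1, so a population distribution collapsed to a
  spike high on that ridge loses nothing in likelihood for any animal and
  the posterior degenerates, over-shrinking everyone upward (the sampler
  itself is calibrated — see the validation section — so this is genuine
  posterior behaviour, a known pathology of hierarchical models with
  one-sidedly flat individual likelihoods). The adopted bounds let the
  population mean reach \(\approx 0.996\) while capping the concentration
  \(a + b\).
* \(\theta \sim U(0, 50)\) km, \(\tau \sim U(0.01, 50)\) km,
  \(\nu \sim U(1.5, 50)\): weakly informative, covering process scales far
  beyond those plausible for a ~40 km/day migrant.
* Initial state: \(x_1 \sim N(y_1, (10\sigma_\varepsilon)^2)\) — proper
  but diffuse at the scale of the data.
* Missing days contribute a state transition but no observation term.

## Sampling and its validation

What matters for any MCMC implementation is distributional correctness,
not algorithmic pedigree. The sampler (C++ via Rcpp) represents the t
shock as a Gamma\((\nu/2,\nu/2)\) scale mixture of normals, which makes
the latent states jointly Gaussian given the mixing precisions; each sweep
draws the full state path exactly by forward-filter backward-sampling,
the mixing precisions from their conjugate Gamma conditionals, and the
remaining parameters by adaptive random-walk Metropolis (γ on the
Fisher-z scale; the beta shapes as logit-mean / log-concentration moves,
which follow the ridge of their joint posterior; adaptation runs during
burn-in only, so the retained chain is a valid fixed-kernel chain). The
default protocol is 2 chains of 40,000 iterations, 20,000 burn-in, thin 5
— 8,000 retained draws — with a split-chain convergence diagnostic on
every free parameter (warning above 1.1).

Three independent checks back the sampler, all in the test suite and
`scripts/acceptance.R`:

1. **Exact-posterior oracle.** With Gaussian process errors the marginal
   likelihood is computable by a Kalman forward filter
   (`coc_loglik_gaussian()`, written independently of the C++ path, and
   itself tested against a dense multivariate-normal evaluation). The MCMC
   histogram over \((\gamma, \sigma)\) matches a \(100 \times 100\) grid
   posterior to total-variation distance well under 0.1.
2. **Rank calibration.** Drawing parameters from the prior, simulating
   data, fitting, and ranking the truth within the posterior draws yields
   uniform ranks (Kolmogorov–Smirnov) over 200 replicates — the
   simulation-based-calibration property a correct sampler must have.
3. **Parameter recovery** on hierarchical synthetic data (next section).

## What the synthetic generator emulates

`coc_sim_spec()` defaults describe a ~3-month, ~3,400 km southward marine
migration tracked by Argos: 7 + 7 animals, 90 daily steps; \(\gamma\)
population centred near 0.975; process scales \(\sigma_j\) around 13 km
(circles of confusion mostly 40–200 km); \(\nu = 3\); ~6 fixes per day
with 2 km per-fix noise and 5% gross outliers (hundreds of km); dwell
phases of localized movement before and after migration; travel rate
elevated about twofold during the departure week, the peak on which
rate-based start detection relies; and optionally an eastward displacement
ramp mid-track imitating the crossing of a strong current. Values were
chosen once to sit in the regime typical of fitted estimates for large
migratory sea turtles (process scale ≈ 13 km, \(\gamma\) ≈ 0.98,
measurement SD ≈ 2 km, individual radii ≈ 40–370 km).

What it deliberately does not emulate: Argos location-class structure
(classes are read but unused — their published standard errors are not
relied on), duty-cycled transmission gaps, oceanographically realistic
current fields, within-migration behavioural switching. Tests passing on
this generator therefore validate the estimator's internal consistency
and the pipeline's robustness properties — not the adequacy of the AR(1)
model for any particular species.

## Pipeline choices worth knowing

* **Regularization.** One location per 24 h window: the mean of the
  minimal-covariance-determinant half-subset (\(h = \lfloor (n+3)/2
  \rfloor\), exhaustive search for \(n \le 12\), concentration steps
  beyond) when a window has ≥ 4 fixes; the coordinate-wise median for 1–3;
  a missing day otherwise. Windows are anchored at the first fix. MCD runs
  on raw degrees — daily windows are local enough that the lon/lat
  anisotropy is far below the fix noise. With a 20% outlier rate and 6
  fixes per day, at least four clean fixes are available on
  \(P\{\mathrm{Bin}(6, 0.2) \le 2\} = 90\%\) of days — the arithmetic
  ceiling on outlier absorption at that contamination level.
* **Migration delimitation.** Start: global maximum of the robust-smoothed
  travel-rate series (running median, default 7-day window, one Hanning
  pass), ignoring the first 7 days, where elevated post-tagging speeds are
  common. End: first reversal of the smoothed day-to-day longitude change
  that persists ≥ 5 days. End detection keys on longitude, so it is
  reliable only when the route has a real longitude trend; with large
  circles of confusion the deviations themselves dominate day-to-day
  longitude change and can fire the detector early. Manual bounds
  (`segment_migration(manual = )`) are therefore first-class, mirroring
  practice with real tracks, where change points are confirmed against the
  mapped track.
* **Route and deviations.** Spherical Earth, \(R = 6371\) km
  (`EARTH_RADIUS_KM`), everything in km. Cross-track distance is to the
  full great circle, not clamped to the start–end arc (the route is a
  reference line; a `clamp` flag exists). The first and last deviations of
  a series are ~0 by construction — the route is tied down at the track's
  endpoints — hence `trim_edges()` (default 2.5% per end) to check that
  the tie-down is not driving the fit.
* **Current-boundary split.** `split_at_boundary()` starts the "after"
  segment at the first location south of the boundary polyline that never
  returns north of boundary + band; a fresh route is then defined from
  that point, which is what re-planning ("drift compensation") means
  operationally.

## Model comparison

`mppl()` implements the squared-error posterior-predictive loss: per
observed deviation, \(G = \sum_l (\mu_l - y_l)^2\) measures fit,
\(P = \sum_l v_l\) penalizes predictive variance, and
\(D_k = P + \tfrac{k}{k+1} G\) (with \(D_\infty = P + G\)) ranks models —
smallest wins, and ranks should be checked across \(k \in \{1, 3, 9,
\infty\}\) (`select_model()` reports a stability flag). Sums run over
every observed deviation of every animal, the observation unit at which
the loss's reference definition operates.

Replicates (`posterior_predictive_replicates()`) condition on the drawn
latent state by default: \(y^{rep}_t = x_t^{(d)} + \varepsilon\). This is
the construction under which the loss has the scale of the measurement
process (a few km² per observation). The unconditional alternative
(`conditional = FALSE`) re-simulates one step from \(x_{t-1}^{(d)}\) and
adds the process-shock variance — hundreds of km² per observation, and
with \(\nu\) near 2 its sample estimate is dominated by the heaviest
draws, making \(D_k\) itself noisy. Users comparing groupings should know
a structural caveat either way: because both the pooled and the
sex-separated models carry individual-level \((\gamma_j, \sigma_j)\), the
grouping changes only hyper-level shrinkage, and simulation shows the
resulting \(D_k\) differences are typically within the statistic's own
noise — a small printed difference between groupings should not be
over-read.

## Problem sizes used in validation

The shipped experiments are scaled to desk size: the grid oracle uses one
animal at \(T = 60\) with 80,000 retained draws; recovery uses 14 animals
at \(T = 90\) with the 2 × 4,000 (burn 2,000, thin 2) protocol; rank
calibration uses 200 replicates at \(T = 20\); the grouping-power and
drift studies use 20 and 10 replicates with single scaled chains. At these
sizes two caveats are measurable and documented rather than hidden: with
\(\gamma \ge 0.95\) and \(T = 90\) the effective information about an
individual's stationary scale is roughly \(T(1-\gamma)/(1+\gamma) \approx
1\text{–}2\) observations, so even the exact posterior median misses the
true radius by more than 30% for roughly a third of animals (the posterior
intervals, in contrast, are calibrated — the hierarchical mean's 95%
interval covers the truth in ~90% of replicates); and the grouping
comparison caveat above.

## Reproducing a full analysis

```{r example, eval = FALSE}
spec <- coc_sim_spec(seed = 1)          # or read_track_fixes("fixes.csv")
study <- simulate_study(spec)
daily <- regularize(study$fixes)        # one robust location per day

migr <- do.call(rbind, lapply(split(daily, daily$animal_id), function(tr)
  segment_migration(tr)$track))
devs <- deviation_series(migr)          # signed km from each animal's route

fit <- coc_fit(devs, grouping = "common",
               control = coc_control(seed = 1))
summary(fit)                            # quantile table incl. predictive rows
plot(fit)                               # per-animal and population radii

fit_sex <- coc_fit(devs, grouping = "by_sex",
                   control = coc_control(seed = 1))
select_model(list(
  Common = mppl(posterior_predictive_replicates(fit, seed = 1)),
  Separate = mppl(posterior_predictive_replicates(fit_sex, seed = 1))))
```
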