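---
title: "Modelling resource- and density-limited bacterial growth and death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling resource- and density-limited bacterial growth and death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsgrowth)
```

## The model

Closed-culture bacterial dynamics pass through exponential growth,
sub-exponential slowdown, a stationary peak and an exponential loss of
viability. `qsgrowth` models the live population $N(t)$ (in fold-change
units, $N(0) = 1$) and a single limiting resource $r(t)$ (normalized,
$r(0) = 1$) with two coupled ODEs:

$$
\frac{dN}{dt} = N \left[ \lambda \,
  \frac{r_0 + K_r}{r_0}\,\frac{r}{r + K_r}\,
  \frac{K_{qs}}{N + K_{qs}} - d \right],
\qquad
\frac{dr}{dt} = -B\,\lambda\,
  \frac{r_0 + K_r}{r_0}\,\frac{r}{r + K_r}\,
  \frac{K_{qs}}{N + K_{qs}}\, N .
$$

The growth law multiplies three factors:

* a **Monod resource factor** $r/(r+K_r)$, normalized by the prefactor
  $(r_0+K_r)/r_0$ so the factor equals 1 at the initial resource level —
  $\lambda$ is then exactly the initial per-capita gross rate;
* a **density-dependent factor** $K_{qs}/(N+K_{qs})$, a phenomenological
  stand-in for quorum-sensing-like growth inhibition ($K_{qs}$ is the
  density of half-maximal inhibition, in fold-change units);
* a constant **death rate** $d$, active in all phases (the model has no lag
  term; cultures are assumed inoculated from mid-exponential growth).

Setting $K_{qs} = \infty$ disables the density factor and yields the
resource-only model; in code the resource-only model *is* this special
case (`model = "R"`), so both share one right-hand side. An optional Hill
exponent $H$ generalizes the resource factor to
$r^H/(r^H + K_r^H)$ with prefactor $(r_0^H + K_r^H)/r_0^H$; $H = 1$
reduces exactly to the Monod form. The prefactor normalization is a design
choice: the source material leaves the Hill prefactor unstated, and
normalizing to 1 at $r = r_0$ keeps $\lambda$'s meaning invariant in $H$.

Resource book-keeping implies a conservation law,
$r_0 - r(t) = B\,(N - N_0 + d \int_0^t N\,ds)$, and a hard yield ceiling
$\max N \le 1 + 1/B$; both are enforced as tests. A third integrated
state, cumulative gross births, underlies the OD generator: optical
density tracks live *plus* dead biomass, so simulated OD is
$OD_0 (1 + \text{births}(t))$ — non-decreasing even while the live count
falls.

### Parameters

| Parameter | Meaning | Units | Typical range |
|---|---|---|---|
| `lambda_max` | maximal per-capita growth rate | 1/h | 0.8–1.5 |
| `d` | death rate | 1/h | 0.01–0.3 |
| `B` | resource consumed per unit growth (1/B = efficiency) | resource/fold | 1e-4–1e-3 |
| `K_r` | resource level of half-effect | resource units | 0–1 |
| `K_qs` | density of half-maximal inhibition | fold-change | 1e2–1e3 |
| `H` | Hill exponent of the resource factor | — | 1 (0.25–20 in the Hill study) |

No published range exists for `d`; the package uses log-uniform 0.01–0.3
1/h where a spread is needed (the order of death rates observed across
natural isolates) and 0.05–0.25 1/h in the recovery study so that
relative-error summaries on `d` are meaningful.

## Numerical choices

Simulation uses an adaptive solver (`deSolve::ode`, lsoda) with a compiled
right-hand side; default tolerances are `rtol = 1e-8`, `atol = 1e-10`
(tightened to `1e-10`/`1e-12` inside fitting objectives so finite-difference
Jacobians are not dominated by solver noise). Negative resource excursions
are prevented by clamping inside the right-hand side — the Monod factor
goes to zero continuously as $r \to 0$, so $dr/dt \to 0$ and any excursion
stays below the absolute tolerance; outputs are additionally floored at
zero. The solver path is validated against an independent fixed-step RK4
integrator written directly from the equations.

Peak summaries (`trajectory_summary`) report the maximal fold change and
its time. For densely simulated trajectories the peak is refined by the
vertex of the parabola through the three log-FC points around the grid
maximum; for sparse observed schedules the grid argmax is reported
unrefined, because observed peak times are resolution-limited (8 h on the
coarse schedule) and pretending otherwise would fabricate precision.

## Rate estimation (stage one)

`estimate_max_growth_rate` scans every contiguous window of at least
`min_window_points` (default 4) points, fits ln(value) against time, and
returns the maximal slope among windows with $r^2 \ge 0.98$ (best-$r^2$
window as fallback). On dense OD grids (97 points at 10-minute spacing)
4-point windows make the max-slope statistic noise-biased upward — the
slope standard error scales as
$\sigma_{\ln}/\sqrt{\sum (t - \bar t)^2}$ — so the pipeline's OD callers
use a 7-point floor (windows spanning at least 1 h), which centres the
estimator.

`estimate_death_rate` locates the peak as the argmax of the median-smoothed
curve and then takes the *steepest* log-linear decline window within the
post-peak segment (minimum 4 points, $r^2 \ge 0.8$, full-segment fallback).
The windowing matters: the model's per-capita rate approaches $-d$ only
after the growth factors have vanished, so fitting the whole post-peak
tail dilutes the decline with the near-flat early-stationary plateau and
underestimates $d$ badly. The lower $r^2$ threshold reflects that decline
signals are shallow relative to scale-proportional counting noise.

## Model fitting (stage two)

`fit_model` minimizes the sum of squared fold-change residuals at the
observation times with bounded Levenberg–Marquardt (`minpack.lm`) on
log10-transformed parameters. Defaults follow the study protocol:

* **Two-stage** (`two_stage_fit`): `lambda_max` fixed from OD, `d` fixed
  from the CFU decline, `{B, K_r, K_qs}` free. A free-all mode exists
  (`fixed = character()`).
* **Multi-start**: 8 starts — the data-driven heuristic
  ($B \approx 1/\mathrm{maxFC}$, $K_{qs} \approx \mathrm{maxFC}/3$), a
  start with `K_qs` at its upper bound so the nested resource-only optimum
  is always reachable, and seeded log-uniform draws over the bounds. Best
  final RSS wins; fits are bitwise reproducible given the seed.
* **Bounds**: the broad study ranges widened tenfold on each side.
* **Residual scale**: linear fold change by default (the scale the study
  fit on); a log-residual option exists because fold changes span decades.
* **Uncertainty**: 95% CIs from the linearized covariance
  $\hat\sigma^2 (J'J)^{-1}$ at the optimum; a free parameter whose CI
  spans its entire bound interval is flagged non-identifiable rather than
  silently reported — growth-only curves flag `d` this way.

AIC and BIC use the Gaussian concentrated-likelihood least-squares forms,
$n \ln(\mathrm{RSS}/n) + 2k$ and $n \ln(\mathrm{RSS}/n) + k \ln n$
(small-sample AICc also reported). `compare_models_dataset` summarizes
criterion differences across curves and adds a two-sample
Kolmogorov–Smirnov test between the two models' criterion values.

## Feasibility mapping

`sample_phase_space` draws parameters (log-uniform for `d`, `B`, `K_qs`;
uniform for `lambda_max`, `K_r`, `H`), simulates to 56 h and records peak
summaries; `region_boundary` bins points by log10 max-FC (50 bins) and
takes per-bin min/max peak times — an envelope rather than a convex hull
because the attainable set is visibly non-convex. Two range presets ship:
`fig3b` (the broad ranges) and `s4fig` (the Hill study: `B` to 1e-5,
`K_qs` to 1e5, `H` 0.25–20).

The falsification study makes two deliberate choices. First, the
resource-only region holds `d` fixed at 0.05 1/h: the death rate is not
among the varied region parameters, and peak placement is insensitive to
death on these scales; letting `d` range widely would pad the region with
slow-net-growth trajectories and blunt the comparison. Second, the region
is built from summaries pushed through the *same* coarse 9-point
observation grid as the observations (`obs_grid`), so grid-resolution
artifacts cannot manufacture either outsideness or coverage: membership
is then tested exactly, with margins in hours for judgement against the
8 h sampling interval. Density-model observations keep a natural
death-rate spread (log-uniform 0.01–0.3); the resource-only null draws
from the region's own ensemble, which is what makes it a null check of
the machinery. Around 40–75% of density-model draws (typically ~60%) fall
outside, depending on the seed of the 20-observation experiment; the null
stays inside throughout. A pointwise caveat on the Hill variant: at fixed
$K_r$, peak time is not monotone in $H$ (it is unimodal, maximal near
$H \approx 2$–10); the attainable upper time grows with $H$ only when
$K_r$ near 1 is allowed, which is the region-level property the tests
assert.

## Synthetic data

The generator emulates the study design, not just the model: 11–12 strains
in three dynamic classes, 3–7 replicates per strain (drawn uniformly, as
in the unbalanced real design), CFU sampled on the coarse 9-point (56 h)
or fine 11-point schedule, OD every 10 min for 16 h from OD 0.05, inocula
of 1e6 cells. The fine schedule's horizon is 26 h
({0,1,2,5,8,11,14,17,20,23,26}); the source states its start pattern and
count but not its end. CFU noise is multiplicative lognormal with unit
median and coefficient of variation `noise_cv` (counts span four decades;
residual spread is scale-proportional; plating/counting noise is folded
into `noise_cv` rather than modelled separately). OD noise is additive
Gaussian (`noise_sd`, default 0.003 — typical plate-reader read noise).

The three archetype classes are parameterized so that they show the
distinct dynamics that define them: *blue* strains (inefficient growers /
strong communicators: $K_{qs}$ 80–130, $1/B$ 250–400, $d$ 0.02–0.04) peak
low and die slowly; *red* strains (efficient but rapidly dying: $1/B$
6500–8000, $d$ 0.25–0.29, $K_{qs}$ 520–580) peak intermediate and crash;
*green* strains (efficient growers / poor communicators: $K_{qs}$
650–950, $1/B$ 4500–6000, $d$ 0.05–0.08) reach the highest fold changes.
The sub-ranges are deliberately tight within each class: the defining
empirical structure is that class members share a trajectory shape, and
two physical couplings otherwise destroy separability — a wide
within-class death-rate range spreads late-time log-FC by decades, and
after a density-limited peak the resource drains on a timescale
$\sim 1/(B \lambda K_{qs})$, so tail shapes require $B$, $\lambda$,
$K_{qs}$ jointly tight. With these settings, hierarchical clustering
(squared Euclidean on log10 median trajectories, average linkage, the
study's own method) recovers the three classes with median adjusted Rand
index 1.0 over seeds at `noise_cv = 0.15`.

What the generator does *not* emulate: detection floors and long-term
stationary-phase survivors (real CFU curves flatten at low counts; ours
decline indefinitely), plate-position effects, calibration non-linearity
in OD, and biological correlations beyond the class structure. Passing
tests therefore show that the *pipeline* is correct and well-calibrated
under the stated noise model, not that real data will match it.

## Two-stage protocol in the studies

The recovery and model-selection studies estimate stage-one rates from
the measurements a real experiment would use: $\lambda$ from the paired
OD time course (dense early sampling; OD is blind to death) and $d$ from
a paired 56-hour coarse-schedule CFU curve — the fine 26-hour schedule
truncates the death phase for much of the parameter space (median peak
time ~18 h), which is precisely why the real design pairs both schedules.
Fitting all five parameters freely was evaluated for model comparison and
rejected: freeing $\lambda$ and $K_r$ lets the resource-only model mimic
density-delayed curves, weakening the criterion discrimination the
two-stage protocol shows cleanly.

## Problem sizes

The shipped studies run at desk scale on one CPU: 20 recovery panels
(5+3+3 replicates each), 10^4-sample regions with 20 observations per
generator, 30 curves per generating model for model selection, and 10
clustering panels — about four minutes end to end, with the full test
suite near two.

## Known limitations

* `K_qs` recovery sits near 15–25% median relative error under the stated
  noise: the density factor shapes only the approach to the peak, and its
  information content is limited at 11 points per curve.
* The falsification outside-fraction for 20 density-model draws straddles
  60% across seeds (binomial noise around a ~0.6 mean); the claim is about
  the typical fraction, not any single panel.
* Death rates are non-identifiable from growth-only curves; the fit flags
  this rather than failing, and downstream medians simply lose those
  replicates.
* The phenotype PCA conventions (log10 then z-score per variable, versus
  z-score only) change variance fractions by several points; both modes
  are always reported because the convention behind printed headline
  fractions in this literature is frequently ambiguous.
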