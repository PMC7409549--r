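---
title: "Models and methods behind spliffr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliffr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliffr)
```

This vignette documents the models, parameter choices and numerical decisions
in spliffr: what is computed, why the defaults are what they are, and what
the synthetic validation does and does not demonstrate about real data.

## The conversion statistic

The SPLIFF reporter is an mCherry–Cub–GFP (CCG) fusion on the bait. A
bait–prey interaction reconstitutes ubiquitin, ubiquitin-specific proteases
cleave behind Cub, and the released GFP is rapidly degraded while the
mCherry-bearing cleavage product persists. Quantification uses three ROIs per
frame and channel — the site of interest, a cytosolic region, and an
extracellular background region. Two reductions are exposed:

* `relative_intensity()`, the comparative-localization ratio
  $(I_{\mathrm{roi}} - I_{\mathrm{bg}})/(I_{\mathrm{cyt}} - I_{\mathrm{bg}})$,
  for comparing a protein's enrichment between strains; and
* `localized_intensity()`, $FI = I_{\mathrm{roi}} - I_{\mathrm{cyt}}$, the
  intracellular-background subtraction that feeds the conversion statistic.

Each channel's $FI$ is normalized to the last frame before cell fusion
(`normalize_to_prefusion()`; a mean over the last $k$ pre-fusion frames is
available but the single-frame reference is the default, since fusion is
detected to one frame and earlier frames can still change focus). Conversion
is

$$FD(t) = 100\,\frac{RFI_{\mathrm{red}}(t) - RFI_{\mathrm{green}}(t)}
{RFI_{\mathrm{red}}(t)} \quad [\%],$$

the fraction of reporter already cleaved at time $t$. $FD$ is invariant to
common gain changes in both channels and, through the subtraction steps, to
common additive offsets; both invariances are asserted in the test suite over
randomized inputs. Whether the ROI readout is an integrated density or a mean
gray value is immaterial at fixed ROI area — the area factor cancels in
$RFI$ — and this area-invariance is asserted rather than assumed. Negative
$FD$ values (pure noise around zero conversion) are retained for curve
fitting and only flagged; values at or above 80% carry an interpretability
caveat flag because little intact reporter remains to convert.

## Population curve and sliding-window trend test

Single-cell traces are pooled in continuous time and fitted with loess
(locally weighted quadratic regression, tricube weights; span 0.25 by
default, i.e. each local fit sees a quarter of all pooled points — narrow
enough to track a 10–15 min interaction window at 2-min sampling of 20 cells,
wide enough to keep the band stable). The 95% band is pointwise, from the
fit's standard errors and a t quantile.

Interaction evidence is a significantly positive trend over **two sampling
intervals**, i.e. three consecutive grid points, advancing one point at a
time. At this window size any smooth trend model degenerates to a straight
line, so the trend is estimated by ordinary least squares. Two modes exist:

* default — the line is fitted to the *pooled raw replicate values* inside
  the window; the loess curve supplies only the window's mean conversion.
  Testing raw replicates keeps the biological and measurement scatter in the
  standard error.
* `on_fitted = TRUE` — the line is fitted to the loess curve's fitted values
  at the replicate time points. This mode reproduces the two-stage
  smooth-then-test description exactly but understates uncertainty (the
  smoothed line has far less variance than the data), which inflates
  significance under the null; it is therefore not the default.

The slope estimator equals the closed-form OLS solution on every window
(asserted against an explicit normal-equations oracle at $10^{-10}$), and the
two-sided P-value comes from the trend coefficient's t statistic. No
multiple-testing correction is applied across windows by default — calling is
per-window at $P < 0.05$, matching the assay's reporting convention; the
window grid makes adjacent windows share two of three points, so corrections
would be strongly conservative anyway.

## Calling rules

A window is called an interaction when

* mean conversion $< 70\%$: slope $\ge 1$ %/min (inclusive) and $P < 0.05$;
* mean conversion $\ge 70\%$: slope $> 0$ and $P < 0.05$;

and the same criterion is **not** met by the negative control (a
non-interacting Nub fusion) in the same window. Stars follow
$P < 0.001/0.01/0.05$. The slope floor reflects that at low conversion a
large reporter pool is available, so a true interaction converts quickly;
near exhaustion any detectable positive trend is meaningful, hence no floor
above 70%. One consequence, visible in degenerate inputs: on *exactly*
noiseless data above 70% the rule calls any infinitesimally positive
deterministic tail (its P-value is 0), so perfect-information tests must keep
conversion below the switch. Real data always carry noise and are unaffected.

## The synthetic-data generator

No raw data are deposited with the originating study, so the package
simulates the experiment forward from a minimal mechanism. The study itself
specifies no kinetic model; a linear three-species system is the simplest
mechanism consistent with cleavage followed by rapid GFP degradation:

$$\frac{dU}{dt} = s - (k_{cl}(t) + d_r)\,U,\qquad
\frac{dR_c}{dt} = k_{cl}(t)\,U - d_r R_c,\qquad
\frac{dG_c}{dt} = k_{cl}(t)\,U - d_g G_c,$$

with $U$ the intact reporter, $R_c$ the cleaved red-bearing product, $G_c$
the free GFP; red signal $\propto U + R_c$, green $\propto U + G_c$.
$k_{cl}(t)$ switches between `cleavage_rate_on` inside scheduled interaction
windows and a basal `cleavage_rate_off` outside them; before fusion no
cleavage occurs and $U$ is held at its steady state. Measurement emulates the
acquisition: the site ROI carries `roi_fraction` of the signal, the cytosol
the rest, each channel is dimmed by a cumulative per-exposure bleach factor,
background is added, and i.i.d. Gaussian noise corrupts every reading.

Default parameters (the package's standard study conditions):

| parameter | default | rationale |
|---|---|---|
| `initial_reporter` | 1000 units | arbitrary brightness scale |
| `synthesis_rate` | 0 /min | the promoter-driven pool is made before mating; with synthesis off, conversion can only accumulate. Continued synthesis is simulable (`synthesis_rate > 0`) since the truth is not known |
| `cleavage_rate_on` | 0.05 /min | gives 2–5 %/min conversion rises in active windows, the scale at which the assay operates |
| `gfp_degradation_rate` | 1.0 /min | "rapid" degradation: sub-minute half-life, ~1–2 frame reporting lag |
| `reporter_degradation_rate` | 0.003 /min | mCherry is long-lived; turnover is mostly dilution (~4 h half-life) |
| `bleach_per_exposure` | 0.002 | exposures are deliberately short to minimize photobleaching |
| `background_level`, `noise_sd` | 50, 8 units | ~2–3 percentage points of single-cell FD scatter, typical of bright reporters under SUM-projected 5-slice stacks |
| `roi_fraction` | 0.85 | polarity proteins are strongly enriched at the cap/neck relative to the cytosol |
| sampling | every 2 min (3 and 5 supported), 115 min, fusion jitter SD 1 min | one cell cycle at the standard frame rate |

The standard benchmark (`standard_benchmark()`) places one true interaction
window in each measurement phase — (6, 18) in PCDI, (44, 56) in PCDII,
(100, 110) in PCDIII — chosen so the scored windows span the regimes the
calling rules distinguish: steep low-conversion rises, mid-conversion slopes
near the 1 %/min floor, and shallow positive trends above the 70% switch.
These conditions were fixed by a pilot power analysis before the validation
thresholds were asserted, and are not adjusted thereafter.

**Integrator.** Within each constant-rate segment the system is linear, so
the classical fixed-step RK4 update is the exact affine map
$x \mapsto Mx + c$ with $M = \sum_{j=0}^{4} (hA)^j/j!$; segments are
subdivided to steps of at most 0.05 min, capped further so that
$h\,\lambda_{\max} \le 0.2$ for the fastest decay mode (explicit RK4 is
unstable for $h\lambda > 2.8$; rapid GFP turnover would otherwise blow up).
Trajectories agree with the closed-form piecewise solution to better than
$10^{-6}$ relative error across randomized schedules, and sampling times are
integration nodes, so no interpolation error enters downstream.

**Benchmark scoring.** `recover_schedule_benchmark()` labels a sliding
window positive when its midpoint lies inside a true interaction window, and
excludes windows whose midpoint falls within one sliding-window width
(4 min) of a true boundary: 2-min sampling, 1-min fusion jitter and the GFP
reporting lag make those windows ambiguous by construction. On the standard
benchmark, calls recover the truth with F1 ≥ 0.9 (F1 = 1.0 at the default
seed), and across 200 cleavage-free populations the per-window false-call
rate stays below $\alpha$ plus three binomial standard errors (the slope
floor makes the rule conservative; observed rates are ~1–3%). The null runs
use 10 cells per population, a deliberate problem-size choice that keeps 200
replicates fast while leaving per-window power realistic.

**What passing these tests does and does not show.** The generator emulates
interaction-gated first-order cleavage, additive Gaussian noise, uniform
per-exposure bleaching and frame-grid jitter. It does not emulate focus
drift, segmentation/tracking errors, fluorophore maturation, spatial
heterogeneity of the ROI, Poisson photon statistics, or cell-to-cell kinetic
variability beyond fusion-time jitter. Recovery results therefore validate
the *pipeline arithmetic and inference logic*, not the biological error
budget of a real experiment; at roughly double the default noise the
benchmark F1 degrades markedly (the floor rule loses power near 1 %/min
true slopes).

## FRAP

`double_normalize()` performs the standard two-step normalization: the ROI
signal is divided by a reference (whole-cell or unbleached-region) signal at
every frame, correcting acquisition photobleaching — the simulator applies
acquisition bleaching to ROI and reference alike, since whole-cell bleaching
affects both, which is exactly why the ratio cancels it — and the ratio is
then rescaled so the pre-bleach mean is 1 and the first post-bleach frame is
0. A trace whose ratio drops less than 10% at the bleach frame is rejected
("no bleach detected"); recoveries exceeding the pre-bleach level are
flagged.

`fit_one_phase()` fits the one-phase association model
$F(t) = Y_0 + (P - Y_0)(1 - e^{-kt})$ by Levenberg–Marquardt least squares
over the post-bleach frames, $t = 0$ at the first post-bleach frame, with a
six-point multistart grid over $k$ (half-times from 2% to 100% of the
recording) keeping the best converged fit. The baseline $Y_0$ is free, as in
the standard one-phase association model of common fitting software: the
full-scale normalization anchors the trace to a *measured, noisy* frame, and
a fixed-through-zero model converts that anchor noise into rate bias, while
a free baseline absorbs it. $t_{1/2} = \ln 2 / k$ holds as an exact identity;
the plateau estimates the mobile fraction and is reported but is a free
parameter, not a constraint. Noiseless round trips recover generating
half-times to <0.1%; at `noise_sd = 0.05` (normalized units, ROI only — the
reference is averaged over a large region and treated as noise-free) the
median half-time error over seeded replicates is ~3%, near the Cramér–Rao
bound for a three-parameter exponential at this noise. Simulated recordings
default to 100 frames at 0.9 s (~90 s, ten half-times at the wild-type-scale
rate), with 4 pre-bleach frames.

`compare_groups()` reproduces the normality-routed testing scheme:
D'Agostino–Pearson omnibus $K^2$ per group (implemented from the published
skewness and kurtosis approximations, verified against an independent
reference implementation; it requires $n \ge 8$, so smaller groups route to
the rank-based tests), then pooled-variance t test or Mann–Whitney U for two
groups and one-way ANOVA or Kruskal–Wallis for more, reporting means ± SEM
and the star convention. Groups with $n < 3$ are excluded with a warning.

## Degenerate inputs and numerical conventions

* Half-open phase intervals $[start, end)$; a timepoint on a boundary belongs
  to the later phase. Time is minutes after cell fusion.
* A near-zero denominator in `relative_intensity()` (below `1e-8` by
  default) yields a flagged `NA` timepoint, not an error; `conversion()`
  returns `NA` for non-positive red RFI.
* Cells without pre-fusion frames or with a zero reference are excluded with
  a logged reason, never silently dropped.
* Sliding windows with fewer than two distinct time values are skipped with
  a message; a zero-residual window (exact collinearity) gets $P = 0$.
* All simulation entry points are deterministic under a fixed seed; per-cell
  seeds derive from one master seed and stay within the 32-bit range.

## Known limitations

* The kinetic model is deliberately minimal: no fluorophore maturation, no
  diffusion between ROI and cytosol, no Poisson noise option.
* The 95% loess band is pointwise, not simultaneous; it supports the figure,
  not the calling rules.
* Calling power drops steeply when true slopes approach the 1 %/min floor at
  mid conversions — a property of the rule, not of the implementation.
* FRAP fitting assumes a single exponential; reaction–diffusion recoveries
  and two-component exchange are out of scope.
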