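---
title: "Quantifying microglial calcium signaling, motility, and morphology with mgca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial calcium signaling, motility, and morphology with mgca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgca)
library(dplyr)
```

## The problem

Microglia — the resident immune cells of the brain — patrol their
environment with motile processes and respond to purinergic signals such as
ADP with cytosolic Ca²⁺ elevations, increased migration, and process
extension. Experiments that probe this biology produce four kinds of
quantitative raw material:

1. **Two-channel fluorescence time series** from ratiometric Ca²⁺ reporters
   (GCaMP6f/tdTomato "Salsa6f", or Fluo-4/Fura-red), one trace per cell;
2. **Cell tracks** exported from tracking software, as (x, y) positions in
   µm at a fixed frame interval;
3. **Image fields** of GFP-labelled cells, for morphological scoring of
   ramification; and
4. **Dose series** of per-cell peak responses, for receptor pharmacology.

`mgca` implements the complete quantification pipeline for these data:
ratio-trace metrics, track motility statistics with a persistent-random-walk
model, simultaneous Ca²⁺–speed coupling analysis, and skeleton-based
process-morphology scoring. Every stage is paired with a seeded synthetic
data generator with exactly known ground truth, so the whole pipeline is
testable end to end without any imaging data.

## Ratiometric Ca²⁺ traces

The ratio trace is built as

$$R(t) = \frac{\langle G(t) - b_G \rangle_w}{\langle R_\mathrm{red}(t) - b_R \rangle_w},$$

where $\langle\cdot\rangle_w$ is a centered rolling average over `w = 3`
frames and $b_G, b_R$ are scalar channel backgrounds. Two numerical choices
are ours: the rolling window is **centered** (a trailing window would lag
the peak by one frame), and it **shrinks at the trace edges** rather than
padding. From the ratio trace we compute:

* **baseline** — the mean of the `k = 10` *smallest* pre-stimulus ratio
  values. Using minima rather than the pre-stimulus mean makes the baseline
  robust to spontaneous pre-agonist transients.
* **peak response** — max ratio in a post-stimulus window minus baseline,
  floored at 0. The window defaults to 120 s; without a cap, the
  store-operated plateau of a slowly rising trace would be scored as its
  "peak". The cap is configurable because no standard value exists.
* **sustained response** — ratio at the frame nearest stimulus + 300 s,
  minus baseline; the store-operated entry (SOCE) component.
* **SOCE rate** — after Ca²⁺ add-back, the maximum of
  $(R(t_0 + w) - R(t_0))/w$ over all frame-aligned windows; $w$ is the
  smallest whole-frame span ≥ 10 s and the rate divides by the true span,
  so a 3-s frame interval yields a 12-s window and an honest denominator.
* **AUC** — trapezoidal integral of $\max(R - \mathrm{baseline}, 0)$.
  Clipping at zero is our choice; sub-baseline excursions are noise in this
  assay and should not cancel genuine release.
* **responder** — peak ≥ max(3 × robust SD of pre-stimulus ratios,
  0.05 Δratio), inclusive. The robust SD (scaled MAD) makes the rule
  scale-free; the absolute floor keeps a noiseless flat trace from being
  scored as responding. Both constants are exposed because no published
  criterion exists.

Population dose–response data are fitted with the four-parameter Hill curve
$r(d) = b + (t - b) / (1 + (EC_{50}/d)^{h})$ by least squares on per-dose
means, weighted by inverse squared SEM when every dose has ≥ 3 cells.
$EC_{50}$ and $h$ are fitted on the log scale, which enforces positivity
without constrained optimization. A flat response profile returns a fit
flagged non-convergent rather than an error.

```{r hill}
pop <- simulate_dose_response(c(10, 30, 100, 300, 1000, 3000),
                              ec50 = 100, hill_coef = 1.5, seed = 1)
fit_hill(pop$cells)
```

## Motility: track metrics and the persistent random walk

Per track, with positions $p(1..n)$ at uniform interval:
track displacement length $TDL = |p(n) - p(1)|$, track length
$TL = \sum_t |p(t) - p(t-1)|$, duration $TD$, straightness $TDL/TL$
(defined as 0 for a track that never moves), mean speed (mean of
instantaneous frame-to-frame speeds, reported in µm/min), and the 10-min
displacement $600 \cdot TDL / TD$. Tracks shorter than 3 min are dropped
(inclusive boundary: exactly 3 min is kept).

The ensemble mean squared displacement uses the **overlapping time-averaged
estimator** per track, then an unweighted mean across tracks; lags are
capped at 50 % of the shortest track because the estimator variance grows
steeply with lag. The persistent-random-walk (PRW) model

$$\mathrm{MSD}(t) = 4D\,\bigl(t - P\,(1 - e^{-t/P})\bigr)$$

is fitted by weighted least squares with weights $n_\mathrm{pairs}/\mathrm{lag}$
(a variance proxy), with $D$ and $P$ log-parameterized. On an exactly linear
MSD the persistence time is not identifiable on the log scale; the fit then
falls back to the Brownian line $4D(t - P)$ with $P$ clamped at ≥ 0, which
is the correct limit.

The **synthetic track generator is exact, not Euler**: per axis the velocity
is a stationary Ornstein–Uhlenbeck process with relaxation time $P$ and
stationary variance $s^2 = D/P$, and each step jointly samples the velocity
update and its exact time integral (the displacement) from their bivariate
Gaussian transition law. Consequently the ensemble MSD equals the closed
form above at *every* frame interval — recovery tests measure the
estimator and fit, not step-size bias.

### Direction autocorrelation and an estimator subtlety

Directional persistence is summarized by the mean cosine of the angle
between displacement vectors separated by a lag (per-pair normalized unit
vectors, pooled over tracks and start points; zero-length displacements
have no direction and are skipped and counted). For an OU velocity the
*per-axis correlation* of displacements decays as $e^{-\tau/P}$ (times a
discretization factor $(\cosh\delta - 1)/(\delta - 1 + e^{-\delta})$,
$\delta = \Delta t/P$). The mean *cosine* is not that correlation: for 2-D
Gaussian vectors with per-axis correlation $\rho$ its expectation is
$\tfrac{\pi}{4}\rho\,{}_2F_1(\tfrac12,\tfrac12;2;\rho^2)$, up to ~0.10
below $\rho$ at intermediate correlations. At fine sampling
($\Delta t \ll P$) the cosine curve therefore sits visibly below
$e^{-\tau/P}$; at $\Delta t$ comparable to $P$ the discretization factor
almost exactly cancels the cosine shrinkage. Our theory-comparison checks
sample tracks at 1-min intervals (a realistic cadence for microglia
time-lapse imaging, $\delta = 0.5$ for $P = 2$ min), where the estimator's
expectation matches $e^{-\tau/P}$ to within ~0.02. This is a property of
the estimator everyone in this field uses, worth knowing when comparing
autocorrelation plots across frame rates.

```{r prw}
tracks <- simulate_prw_tracks(prw_params(D = 5, P = 2, n_tracks = 100,
                                         duration = 1800, seed = 1))
fit_prw(msd_curve(tracks))
```

## Ca²⁺–speed coupling

Salsa6f lines report Ca²⁺ and position simultaneously, giving one (ratio,
speed) sample per cell per frame interval. The pairing convention is ours:
the speed over interval $(k, k+1)$ is paired with the ratio at the frame
nearest the interval **midpoint** (ties to the earlier frame) within a
configurable tolerance — symmetric, and free of look-ahead bias. Unmatched
intervals are dropped and counted, never interpolated.

Samples are pooled across cells (the published pair counts far exceed cell
counts, implying pooling) and summarized by Spearman rank correlation
(average-rank ties; two-sided p by the t approximation for n > 30), by mean
speed in half-open ratio bins of width 0.5 anchored at 0, and by the
percentage of "fast" samples per bin — strictly above 10 µm/min. Empty bins
are reported as missing, not zero.

The coupled-track generator gives each cell a bounded autocorrelated ratio
signal (an OU process with mean 1.2, SD 0.5, 60-s relaxation, clipped to
[0.05, 3]) and sets its target speed to
$\max(0,\; v_0 + \beta\,\mathrm{ratio} + \varepsilon)$ with the direction
evolving as in the PRW. The default $v_0 = 14$ µm/min was chosen so that
with the default slope $\beta = -4$ µm/min per ratio unit the target speeds
stay mostly in the non-clipped linear regime across the ratio range (2–14
µm/min, straddling the 10 µm/min fast threshold); with a smaller $v_0$ the
zero-clipping would flatten the binned means at high ratio and the binned
slope would no longer estimate $\beta$. When estimating that slope from bin
means we only use bins with ≥ 20 samples; sparse edge bins contribute noise,
not signal.

## Process morphology

The morphology stage mirrors the standard Fiji workflow: maximum-intensity
projection (for stacks), a fixed intensity threshold **shared across a
paired pre/post set** (enforced by `binarize_fields()`), noise reduction,
skeletonization, and branch analysis:

* **Despeckle** is the 3×3 binary median. Note that a true median also
  rounds single-pixel convex corners and fills isolated holes — this is
  inherent to the operator, and our tests assert it rather than pretending
  otherwise. A consequence worth knowing: strokes thinner than 3 px are
  erased entirely, which is why the synthetic generator draws 3-px-wide
  branches.
* **Outlier removal** is re-specified deterministically as the removal of
  8-connected foreground components smaller than 4 px.
* **Skeletonization** is Zhang–Suen thinning (topology-preserving, output
  8-connected).
* **Branch analysis** classifies skeleton pixels by their pruned
  8-neighbour count (endpoint < 2, slab = 2, junction > 2; diagonal links
  that shortcut an occupied corner pixel are pruned first so corners do not
  double-count). Branches are maximal slab paths between endpoint/junction
  pixels; orthogonal steps count `pixel_size`, diagonal steps
  `sqrt(2) * pixel_size`. Adjacent junction pixels act as one junction, and
  endpoint spurs shorter than 3 px emanating from junctions — thinning
  artifacts — are pruned (configurable).
* **Process filter**: skeleton components with total length strictly
  greater than 8 µm count as processes; branch and length totals are
  normalized per cell in the field, and pre/post fields compare as fold
  changes (undefined, not infinite, when the pre metric is zero).

The synthetic generator draws star-shaped cells whose branches leave the
soma along 45°-compass directions separated by ≥ 90°. Three deliberate
geometry choices make ground truth exact: compass directions make the
rasterized geodesic equal the polyline length exactly; the ≥ 90° separation
prevents adjacent 3-px strokes from merging near the soma (which would
split one true branch into two measured ones); and random cells carry 3–4
branches because a 2-branch cell thins to a single junction-free path that
branch counting rightly scores as one branch. Single-branch "stub" cells
whose skeleton is shorter than 8 µm exercise the process filter.

Skeleton-measured total length carries a small negative bias (≈ 1–2 px per
branch: thinning erodes stroke tips, and the path starts at the junction
pixel rather than the soma centre). Across random fields this is a stable
≈ 4 % underestimate — within the 5 % envelope we validate, and it cancels
almost entirely in pre/post fold changes.

```{r morph}
field <- simulate_ramified_field(n_cells = 4, n_stubs = 1,
                                 speckle_density = 0.001, seed = 1)
pip <- morphology_pipeline(field$field, threshold = 100, n_cells = 5)
pip$summary
```

## What the synthetic data do and do not show

The generators emulate: biphasic agonist-evoked ratio traces (fast
difference-of-exponentials store-release peak, saturating-exponential SOCE
plateau, multiplicative green-channel noise over a noisy-constant red
channel, matching the behaviour of a ratiometric reporter whose red channel
does not respond to stimulation); Hill-shaped dose–response with a
configurable responder fraction; exact-discretization persistent random
walks; speed–Ca²⁺ coupling with a known slope; and ramified cells with
pixel-exact branch ground truth plus isolated-speckle noise.

They deliberately do **not** emulate: photobleaching and focus drift,
cell–cell contact and overlap, segmentation error in ROI placement,
non-Gaussian flight-like motility, heterogeneous per-cell kinetics, or
curved/tapering processes. Passing recovery tests therefore demonstrates
that the *estimators and pipeline plumbing* are correct at realistic noise
levels — not that any particular biological dataset meets the generators'
assumptions.

Default generator parameters are fixed at realistic study conditions: 2-s
imaging frames, stimulus at 60 s, baseline ratio 0.4, peak amplitude 1.2
with 3-s rise and 25-s decay, plateau 0.4 with 60-s rise, ratio noise SD
0.02; tracks with D = 5 µm²/min and P = 2 min sampled at 15 s for 60 min;
fields of 400² px at 0.5 µm/px. Validation scales are 100 traces, 500
tracks, 100 coupling simulations and 50 morphology fields — sizes at which
Monte-Carlo error is comfortably below the tolerances being checked.

## Known limitations

* Backgrounds are per-trace scalars; per-pixel background subtraction is an
  imaging-time operation outside this package's scope, as is ROI
  segmentation of Ca²⁺ movies and image-based spot detection.
* The greedy mutual-nearest-neighbour spot linker is a reference
  implementation of the stated linking rules (4 µm max jump, 10-frame
  disturbance, no gap filling), not a reproduction of any commercial
  tracker's proprietary logic.
* Skeleton branch counting follows the endpoint/junction graph convention;
  morphologies outside the generator's assumptions (touching cells, loops)
  are handled but not length-validated. Touching cells can be separated by
  supplying a manual mask upstream; no automatic splitting is attempted.
* The Spearman p-value uses the t approximation for large n; for small
  tied samples it defers to `stats::cor.test`.
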