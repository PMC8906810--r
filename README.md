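# mgca

Single-cell quantification of purinergic Ca²⁺ signaling, motility, and
process morphology in iPSC-derived microglia.

Microglia respond to agonists such as ADP with a biphasic cytosolic Ca²⁺
signal — a rapid store-release peak followed by sustained store-operated
entry (SOCE) — and with changes in migration and ramification. Studies of
this biology (for example, comparisons of wild-type and TREM2-knockout
iPSC-microglia) rest on a shared set of quantifications, which this package
implements as a tested, reusable pipeline:

* **Ratiometric Ca²⁺ traces** (`compute_ratio_trace()`, `trace_metrics()`,
  `fit_hill()`): background-subtracted, 3-frame rolling-averaged G/R ratios;
  baseline as the mean of the 10 minimum pre-agonist ratios;
  baseline-subtracted peak; sustained response at +5 min; SOCE rate
  Δ(ratio)/Δt over the steepest 10-s window after Ca²⁺ add-back; AUC;
  responder classification; Hill/EC₅₀ dose–response fits; ΔF/F₀.
* **Motility** (`track_metrics()`, `msd_curve()`, `fit_prw()`,
  `velocity_autocorrelation()`, `link_spots()`): instantaneous and mean
  speeds (µm/min), track displacement length TDL, track length TL,
  straightness TDL/TL, 10-min displacement 600·TDL/TD, the 3-min track
  filter, time-averaged ensemble MSD with the persistent-random-walk fit
  MSD(t) = 4D(t − P(1 − e^(−t/P))), direction autocorrelation, and greedy
  nearest-neighbour spot linking (4 µm max jump, 10-frame disturbance, no
  gap filling).
* **Ca²⁺–speed coupling** (`pair_ca_speed()`, `coupling_summary()`):
  per-cell per-frame pairing of instantaneous G/R ratio with instantaneous
  speed, Spearman correlation, mean speed in 0.5-ratio bins, and the
  percentage of fast-moving cells (> 10 µm/min) per bin.
* **Process morphology** (`morphology_pipeline()`): threshold → despeckle →
  outlier removal → Zhang–Suen skeletonization → branch/length analysis,
  with the > 8 µm process filter, per-cell normalization, and paired
  pre/post fold changes.
* **Synthetic data with ground truth** (`simulate_ca_trace()`,
  `simulate_dose_response()`, `simulate_prw_tracks()`,
  `simulate_coupled_tracks()`, `simulate_ramified_field()`): seeded
  generators for every input type, including an exact-discretization
  Ornstein–Uhlenbeck track simulator whose ensemble MSD matches the PRW
  closed form at any frame interval.

Functions take data frames first and return tibbles, so stages chain with
the pipe; fitted objects support `tidy()`, `glance()`, and `autoplot()`.

## Worked example

Simulate five cells' worth of two-channel fluorescence, rebuild the ratio
traces, and score them:

```r
library(mgca)

sim   <- simulate_ca_trace(ca_trace_params(seed = 42), n_cells = 5)
ratio <- compute_ratio_trace(sim$trace, background_green = 20,
                             background_red = 30)
trace_metrics(ratio, stim_time = 60)
#>   cell_id baseline peak_response threshold responder response_at
#> 1       1    0.392          1.25      0.05      TRUE       0.409
#> 2       2    0.383          1.24      0.05      TRUE       0.408
#> 3       3    0.383          1.23      0.05      TRUE       0.422
#> 4       4    0.386          1.26      0.05      TRUE       0.417
#> 5       5    0.385          1.23      0.05      TRUE       0.423
```

The recovered baselines sit at the generator's 0.4 resting ratio, the
baseline-subtracted peaks at its 1.2 peak amplitude (plus the small rising
SOCE contribution), and the +5 min responses at its 0.4 plateau — the
pipeline reads back what the generator injected, which is exactly what the
test suite verifies at scale.

Track motility and the persistent-random-walk fit:

```r
tracks <- simulate_prw_tracks(prw_params(D = 5, P = 2, n_tracks = 200,
                                         duration = 1800, seed = 42))
fit <- fit_prw(msd_curve(filter_tracks(tracks)))
fit
#> Persistent-random-walk fit
#>   D = 4.965 um^2/min, P = 1.939 min (converged: TRUE)
```

D is the diffusion coefficient (µm²/min) and P the directional persistence
time (min): 200 simulated tracks recover the true (5, 2) to within a few
percent. `autoplot(fit)` overlays the fitted curve on the measured MSD, and
`plot_tracks_at_origin(tracks)` draws the flower plot.

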