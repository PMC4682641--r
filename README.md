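# frapkin

Quantification of FRAP and FLIP experiments on nuclear proteins that exchange
between a free pool, chromatin-bound foci, and an RNA-bound state — built for
HP1-family heterochromatin proteins (such as fission yeast Swi6), which
concentrate in 2–6 bright foci fed by a shared nucleoplasmic pool.

The scientific question these experiments answer is whether such a protein
forms a static scaffold or exchanges rapidly. The package implements the
full measurement chain:

* **Trace extraction and normalization** from multi-page TIFF time series
  (ROI mean per frame → subtract the per-trace minimum → locate the bleach
  frame from the largest intensity drop → normalize to the mean of the last
  15 frames).
* **Recovery fitting**: least squares for `y(x) = a(1 − exp(−bx))` and
  `y(x) = a(1 − exp(−bx)) + c(1 − exp(−dx))`, with the linear parameters
  profiled in closed form (so the fit is structurally equivalent to an
  exhaustive grid search), nested F-test model selection, the half-recovery
  time `t½ = ln 2 / b` (or a numeric solve for two components), and R².
* **Mobile fraction** with the whole-nucleus correction
  `F_M = (F_∞/F_initial) / (total_after/total_before)`, measured on pre/post
  z-stacks so that bleach depletion and axial locus drift do not bias it;
  `F_I = 1 − F_M`.
* **FLIP analysis**: relative fluorescence of bleached, non-bleached, and
  control loci, with a one-sided Welch test for exchange *in trans*.
* **Line-scan FRAP** at ~2 ms resolution: control-normalized region
  intensities, the gliding-average display convention, and offset-anchored
  half-time fits.
* **Cohort statistics**: IQR/1.5-whisker box summaries, Welch's
  unequal-variance t-test, and per-cell-cycle-phase profiles.
* **A three-state stochastic simulator** (free / chromatin-bound /
  RNA-bound, exact event-driven jumps, immobile subpopulations, shot noise,
  axial drift, acquisition photobleaching) with a matrix-exponential
  mean-field oracle — so every estimator is tested against known ground
  truth without any microscope data.

## Worked example

Simulate one heterochromatic FRAP experiment under the default study
conditions (120 frames at 60 ms, 20 ms diffraction-limited bleach of one of
three foci, 10⁴ molecules) and analyze it:

```r
library(frapkin)

cfg <- config_heterochromatin()          # calibrated: expected t1/2 = 535 ms
experiment <- simulate_frap_experiment(cfg, seed = 42)

trace <- extract_trace(experiment$timeseries, experiment$locus_roi) |>
  subtract_background() |>
  detect_bleach_frame() |>
  normalize_trace()

fit <- fit_recovery(trace, model = "one")
fit
#> <recovery_fit> one_component on 110 points
#>   params: a = 1, b = 1.296
#>   t_half = 534.9 ms, R^2 = 0.9911, RSS = 0.04632
```

The fitted rate `b = 1.296 s⁻¹` means a bleached focus regains half of its
steady-state fluorescence in ~535 ms: the protein is a single, highly
dynamic population, not a static network. The mobile fraction confirms full
exchange once the whole-nucleus correction is applied — the raw ratio is
capped at 0.77 only because the bleach destroyed ~23% of all fluorescence:

```r
raw <- detect_bleach_frame(subtract_background(
  extract_trace(experiment$timeseries, experiment$locus_roi)))
corrected_mobile_fraction(raw, experiment$pre, experiment$post,
                          experiment$nucleus_roi, experiment$locus_roi)
#>   raw_ratio correction   f_m   f_i single_plane_ratio
#> 1     0.766      0.768 0.997 0.003              0.737
```

A cohort of 31 experiments, averaged and fitted like a published mean
recovery curve, with the per-cell half-time box summary:

```r
cohort <- simulate_frap_cohort(cfg, n = 31, seed = 7)
glance(cohort$mean_fit)
#>   model         t_half_ms r_squared     rss    aic     n
#> 1 one_component      545.     0.999 0.00330 -1142.   110
summarize_group(cohort$records$t_half_ms)
#>    n median  q1   q3  iqr whisker_low whisker_high n_outliers
#> 1 31   546. 526. 564. 37.5        496.         596.          0
```

`autoplot()` methods produce the standard figures (recovery curve with fit,
FLIP curves, kymographs, phase boxplots); `tidy()`/`glance()` return
broom-style tibbles.

## Package layout

* `R/config.R`, `R/simulate.R`, `R/meanfield.R`, `R/render.R` — the kinetic
  simulator and its deterministic oracle.
* `R/image-io.R`, `R/roi.R` — TIFF/JSON/CSV readers and writers, ROI
  containers (0-based `(row, col)` pixel coordinates).
* `R/trace.R`, `R/fit.R`, `R/fraction.R`, `R/flip.R`, `R/linescan.R`,
  `R/cohort.R` — the analysis pipeline.
* `vignettes/frap-kinetics.Rmd` — the model, its assumptions, parameter
  defaults and their rationale, numerical choices, and known limitations.
* `inst/extdata/` — small example ROI/config/record files for the text
  formats.
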