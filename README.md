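# isfcs — intensity-sorted fluorescence correlation spectroscopy

Fluorescence correlation spectroscopy (FCS) reads concentration and mobility
out of the intensity fluctuations in a confocal observation volume: the
autocorrelation function (ACF)
`G(tau) = <dI(t) dI(t+tau)> / <I>^2` has amplitude `G(0) ~ 1/N` and decays on
the transit-time scale `t_D = w0^2 / (4 D)`. A parked beam, however, reports a
single position — useless for asking how mobility *differs* between the
nucleolus and the nucleoplasm, or between dense and open chromatin, inside one
nucleus.

`isfcs` implements the slow-scanning, segment-sorting answer to that problem,
for people who analyse (or simulate) confocal FCS of spatially heterogeneous
specimens:

1. the beam is scanned on a circular orbit slow enough that it is effectively
   parked on the time scale of the fluctuations (`v << 0.4 D / w0`);
2. the photon trace is cut into segments of duration `T_seg >= 100 t_D`, each
   carrying its own short-sequence ACF and mean intensity per channel;
3. segments are sorted into region populations by intensity thresholds on a
   reference channel (the probe itself or a DNA stain), the mixed interface
   band is discarded;
4. per-population averaged ACFs are fitted — one-component diffusion,
   scanned diffusion, short-sequence (free-offset), global two-component with
   shared diffusion times, or a reaction–diffusion ("full") model yielding
   molecule number, bound fraction and residence time;
5. per-cell region-to-region ratios of `D` are summarised as through-origin
   regression slopes, immune to cell-to-cell variability of the absolute
   values.

A Brownian-dynamics simulator (molecules with region-dependent `D` in a
periodic box, 3D-Gaussian detection, Poisson photons, orbital scanning,
optional photobleaching) provides ground truth for every stage, so the whole
pipeline is validated without any experimental data. An acquisition-design
calculator turns a target `D` and waist into segment-duration and scan-speed
bounds.

## Worked example

Plan the acquisition, then simulate an orbit crossing two regions
(`D = 20` vs `10 um^2/s`, 2:1 reference contrast) and recover the ratio:

```r
library(isfcs)

design_report(D = 20, w0 = 0.2, orbit_diameter = 3)
#> Acquisition design for D = 20 um^2/s, w0 = 0.2 um, orbit diameter = 3 um
#>   t_D = w0^2/4D            = 0.0005 s
#>   T_seg lower limit        = 0.05 s (100 t_D)
#>   scan speed bound v <<    = 40 um/s (0.4 D/w0; segment bound 4, binding bound 40)
#>   recommended v (x10 margin) = 4 um/s
#>   orbit frequency f <<     = 4.244 Hz (period >> 0.2356 s)
#>   conventional scanning FCS would need f > 2000 Hz

cfg   <- two_region_orbit_preset(D_high = 20, D_low = 10, contrast = 2, seed = 1)
trace <- simulate_trace(cfg)          # 16.5 s orbit, 20 us bins, 2 channels
curves <- sorted_acfs(trace, T_seg = 0.1)   # detrend, segment, sort terciles
print(attr(curves, "segments"))
#> Segment set: 165 segments of 0.1 s (5000 bins each), ACFs on 'probe'
#> Labels:
#> discarded      high       low
#>        55        55        55

fits <- lapply(curves, fit_curve, model_id = "ss_1comp", w0 = 0.2)
fits$high
#> FCS fit: model ss_1comp
#>   G0       = 1.9063 +/- 0.0147
#>   tD       = 0.000464431 +/- 1.03e-05
#>   b        = -0.0819516 +/- 0.0034
#>   D        : 21.5317
#>   rss = 33.2, reduced chi^2 = 0.4743 over 73 lags

vapply(fits, function(f) f$derived$D, 0)
#>   low  high
#> 11.96 21.53
```

Reading the numbers: the tercile split on the PSF-smoothed reference channel
labels 55 segments per region and discards the 55 interface segments; the
free-offset fit of each averaged segment ACF absorbs the finite-segment
baseline (`b ~ -0.08`) and returns apparent diffusion coefficients whose
ratio, `D_low / D_high = 0.56` on this single orbit (`0.495 +/- 0.04` over 20
seeds), recovers the simulated 2:1 mobility contrast. The absolute values sit
~10–20% above the inputs because the fitting models are lateral-only while
the simulated volume has `wz/w0 = 4` — a common-mode bias that cancels in the
ratio (see the vignette).

`run_pipeline(config)` drives the same chain from a JSON config and writes
curve tables, fit reports, a label audit and a run manifest;
`reproduce("two_region_recovery")`, `reproduce("bias_scan")`,
`reproduce("speed_bounds")` and `reproduce("ratio_recovery")` re-run the
built-in validation experiments with pass/fail verdicts.

## Layout

- `R/`, `src/` — pipeline and models in R, correlator and Brownian-dynamics
  simulator in C++ (Rcpp)
- `tests/testthat/` — unit, property and end-to-end validation suites
- `vignettes/intensity-sorted-fcs.Rmd` — the models, estimator choices,
  simulator assumptions and their rationale
- `inst/cli/isfcs` — command-line wrapper
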