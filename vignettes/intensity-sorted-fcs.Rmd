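---
title: "Intensity-sorted FCS: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-sorted FCS: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isfcs)
```

## The problem and the method

Fluorescence correlation spectroscopy (FCS) infers concentration and mobility
from the fluctuations of the fluorescence collected in a diffraction-limited
observation volume: the autocorrelation function (ACF)

$$G(\tau) = \frac{\langle \delta I(t)\,\delta I(t+\tau)\rangle}{\langle I\rangle^2}$$

has amplitude $G(0) \propto 1/N$ (inverse of the mean number of molecules in
the volume) and decays on the transit-time scale $t_D = w_0^2/4D$, where $w_0$
is the lateral $e^{-2}$ waist and $D$ the diffusion coefficient.

A single parked measurement reports one position. To map mobility across a
heterogeneous specimen — a cell nucleus with nucleoli, dense and open
chromatin — this package implements *intensity-sorted FCS*: the beam is
scanned on a slow circular orbit so that one acquisition visits many
positions; the photon trace is cut into short segments of duration
$T_{\rm seg}$; each segment yields its own short-sequence ACF (ssACF) and a
mean intensity per channel; segments are sorted into region populations by
thresholding a reference intensity (the probe itself, or a DNA stain); and
the ssACFs of each population are averaged and fitted. Each measurement thus
returns one ACF per region *from the same cell*, so region-to-region ratios
of $D$ are immune to the large cell-to-cell variability of the absolute
values.

## Segment duration: why $T_{\rm seg} \ge 100\,t_D$

A segment must be long enough to sample the fluctuations it is meant to
average. Segment-averaged ssACFs computed from too-short segments are
deformed in a characteristic way: shorter apparent $t_D^s$, a negative
baseline offset $b^s$, and a slightly inflated amplitude $G^s(0)$. The
package quantifies this with `segment_bias_scan()`, comparing the
short-sequence fit

$$G^{s}(\tau) = G^{s}(0)\,\bigl(1+\tau/t_D^{s}\bigr)^{-1} + b^{s}$$

of the segment-averaged curve against the zero-offset one-component fit of
the full-trace ACF on the identical lag grid. At $T_{\rm seg} = 100\,t_D$ the
fitted $t_D$ and $G(0)$ agree to better than 5%, which is where the
package's design calculator places the lower limit
(`min_segment_duration()`).

Two details matter and are deliberate:

* **Estimator.** All ACFs use *symmetric normalization*: at every lag the
  means are computed over the two overlapping windows. This removes most of
  the finite-length amplitude bias; what remains is a nearly constant
  negative baseline of order $2\,G(0)\,t_D \ln(T_{\rm seg}/t_D)/T_{\rm seg}$
  (about $-5\%$ to $-9\%$ of the amplitude at the settings used here).
* **Fit model for segment averages.** Because that residual bias is an
  offset, segment-averaged curves are fitted with the free-offset
  short-sequence model. Forcing $b=0$ on a segment-averaged curve converts
  the offset into an artificially short $t_D$, and does so *asymmetrically*
  between populations whose $T_{\rm seg}/t_D$ differ — in the two-region
  validation this distorted the recovered $D$ ratio from 0.50 to 0.67. The
  zero-offset model is reserved for full-trace ACFs.
* **Lag window.** Segment ACFs run to $T_{\rm seg}/2$ by default. The free
  offset is only identifiable when the window resolves the baseline; with a
  $T_{\rm seg}/4$ window the offset–$t_D$ trade-off roughly quadrupled the
  $t_D$ deviation at $T_{\rm seg} = 100\,t_D$.

## Scan speed: how slow is slow

Scanning adds a decorrelation term. For a circular orbit of radius $R$ and
period $T$ (speed $v = 2\pi R/T$) the scanned free-diffusion ACF is

$$G(\tau) = G(0)\,(1+\tau/t_D)^{-1}
  \exp\!\left(-\frac{4R^2}{w_0^2}\,
  \frac{\sin^2(v\tau/2R)}{1+\tau/t_D}\right),$$

which for lags far below the orbit period reduces to the small-angle form
with $v^2\tau^2/w_0^2$ in the exponent (`eval_model("scan_diff")` /
`"scan_diff_approx"`; both collapse exactly to the parked model at $v = 0$).
Beam motion is negligible over one segment when $v \ll w_0/T_{\rm seg}$ and
$v^2 \ll w_0^2/(t_D T_{\rm seg})$. With the rule $T_{\rm seg} = 100\,t_D$
the second bound becomes $v \ll 0.4\,D/w_0$ — for $D = 20\ \mu m^2/s$ and
$w_0 = 0.2\ \mu m$, $v \ll 40\ \mu m/s$, i.e. an orbit frequency well below
4 Hz on a 3 µm orbit. For contrast, conventional scanning FCS (correlating
successive passes) would need line rates *above* $1/t_D \approx 2$ kHz.
`max_scan_speed()` reports both sub-bounds and, when an explicit
$T_{\rm seg}$ is given, returns their minimum; the "much less than" margin
is reported (default ×10) rather than silently applied, because the
trade-off between margin and photon budget is an experimental judgment.

## Sorting and detrending

Segments are labeled by threshold rules on per-segment mean intensities
(`sort_rule()`, `clause()`): *below* means mean ≤ threshold, *above* means
mean > threshold, so a two-sided pair of rules leaves the interface band
unlabeled — those segments mix both regions and are discarded, matching how
the method is used in practice. Thresholds may be absolute or percentiles of
the observed segment means; the default is a tercile split on the reference
channel (below the 33rd / above the 67th percentile), with the middle third
discarded. Overlapping rules are an error, not a precedence: silent
precedence would make results depend on rule order. A percentile split on a
channel whose tercile gap is within shot noise of a homogeneous specimen
triggers a warning — sorting such a trace is meaningless (this is also the
degenerate 1:1-contrast case).

Slow drifts — photobleaching above all — corrupt both thresholds and
amplitudes, so traces are detrended before sorting. The default method fits
$a\,e^{-t/\tau_b}+c$ on a coarse intensity profile, divides it out and
rescales to the original global mean (counts stay non-negative integers; the
fit is attempted only when a head-to-tail trend is visible above the profile
noise). A moving-average-division variant exists, but on scanned traces any
window shorter than the orbit period removes the *genuine* spatial intensity
structure along the orbit — the package warns in that situation. This is why
the parametric detrend is the default for the sorting pipeline: it removes a
bleaching-like monotone decay while leaving orbital structure intact.

## The simulator

`simulate_trace()` is the package's ground truth: point molecules take
independent Gaussian steps (Euler–Maruyama, sub-steps chosen so
$\Delta t \le t_D/100$ for the fastest region) in a periodic box tiled into
regions of different $D$, brightness scale and reference rate; the detection
profile is a 3D Gaussian $W(\mathbf r) = \exp(-2(x^2+y^2)/w_0^2 -
2z^2/w_z^2)$ centred on a parked or orbiting beam; probe counts are Poisson
with the per-bin integral of brightness-weighted $W$; the reference channel
is Poisson with the PSF-weighted blend of region rates at the beam position
— a boundary therefore appears error-function-smooth in the reference trace,
exactly as a stained structure does through a real objective, which is what
lets the tercile interface band discard spatially mixed segments. Optional
photobleaching removes molecules with per-step survival
$\exp(-k_b W \Delta t)$, i.e. preferentially where excitation is high.

Choices a user should know about:

* **Occupancy.** Presets use the smallest box the sanity constraints allow
  (10 lateral waists, 4 axial waists) and particle numbers giving
  $G(0) \approx 0.8$–$1.2$ — about one molecule in the volume, the ordinary
  single-molecule FCS regime. This is not cosmetic: the finite-segment bias
  grows with $G(0)\,t_D/T_{\rm seg}$, and at amplitudes far above 1 (fractions
  of a molecule in the volume) per-segment normalization degenerates — the
  $100\,t_D$ rule presupposes ordinary amplitudes.
* **Axial ratio.** The fitting models are 2D-lateral, as is standard for
  elongated confocal volumes; the simulator's default $w_z/w_0 = 4$ leaves a
  slow axial decay that biases absolute fitted $D$ upward by roughly
  10–20% depending on the lag window. The bias is common mode: it cancels in
  the region-to-region ratios this method exists for (and in the
  segment-bias deviations, which compare two fits of the same data).
  Closed-form recovery tests — and the segment-bias experiment, whose
  deformation is *defined* against the lateral-only models — use
  $w_z/w_0 \gg 1$, where the axial term vanishes (at $w_z/w_0 = 4$ the axial
  tail leaks into the free-offset/zero-offset fit comparison and both
  inflates and destabilises the apparent $t_D$ deviation). Outputs record
  the ratio used.
* **Itô convention.** Steps are drawn from the diffusion coefficient of the
  region the particle currently occupies. The stationary density of this
  process is $\propto 1/D$, so slow regions hold proportionally more
  molecules and sorted populations differ in amplitude; this mirrors the
  concentration differences real compartments show and does not touch the
  transit times.
* **Reference realism not modeled.** The reference is a deterministic field
  sampled at the beam position — it does not diffuse, bleach, or fluctuate
  beyond shot noise. Passing tests therefore validate segmentation, sorting
  and fitting, not robustness to a moving reference structure.

## Two-component and reaction–diffusion fits

For probes that bind, two models are provided. The two-component diffusion
model $G(\tau) = G_{slow}(0)(1+\tau/t_{D,slow})^{-1} +
G_{fast}(0)(1+\tau/t_{D,fast})^{-1}$ is fitted *globally*
(`global_fit_2comp()`): the two diffusion times are shared across all curves
of an experiment while amplitudes vary per curve, and the slow fraction
$SF = G_{slow}(0)/(G_{slow}(0)+G_{fast}(0))$ is reported per curve. Shared
times within a factor two of each other are flagged as degenerate.

The *full model* (`full_model_acf()`, `fit_full_model()`) treats one species
diffusing with coefficient $D$ that binds immobile sites with
pseudo-first-order rate $k^*_{on}$ and unbinds with $k_{off}$, both bound and
free molecules fluorescing. Linearized kinetics give, per radial spatial
frequency $q$, a two-mode relaxation through
$M(q) = \begin{pmatrix} -(Dq^2+k^*_{on}) & k_{off}\\ k^*_{on} & -k_{off}
\end{pmatrix}$, and

$$G(\tau) = \frac{1}{N}\int_0^\infty 2u\,e^{-u^2}\,
  \mathbf 1^\top e^{M(2u/w_0)\tau}\,\mathbf p\;du, \qquad
  \mathbf p = (F_{eq}, B_{eq})^\top,$$

evaluated by Gauss–Legendre quadrature on $u \in [0, 6]$ (200 nodes; the
pure-diffusion limit then integrates exactly to $(1+\tau/t_D)^{-1}$, and
doubling the node count changes values by $<10^{-10}$). Derived quantities:
bound fraction $BF = k^*_{on}/(k^*_{on}+k_{off})$ and residence time
$RT = 1/k_{off}$. The amplitude convention is $G(0) = 1/N$ with no shape
factor, and $N$ is reported in those model units. Two limits anchor the
implementation: $k^*_{on} \to 0$ reproduces pure diffusion at every lag, and
in the reaction-dominant regime ($t_D \ll 1/k_{off}$, substantial bound
fraction) the tail decays at rate $k_{off}$. Note the regime logic: binding
kinetics are invisible when diffusion is *slow* (total occupancy is then
conserved), not when it is fast. Fits of curves that have not decayed to
baseline are flagged `qualitative = TRUE` and should be read as trends only.

## Ratios, spot variation, numerics

Per-cell ratios are estimated by `ratio_slope()`: the slope through the
origin, $\hat s = \sum x_i y_i / \sum x_i^2$, of region-2 versus region-1
diffusion coefficients across cells, optionally summarised as mean ± SD of
per-experiment slopes. Spot-variation analysis (`spot_variation()`)
regresses apparent $D$ on the squared effective waist across observation
volumes of different size; a slope interval containing zero is consistent
with free diffusion.

Numerical conventions, all recorded in run manifests: multi-tau correlator
with 8 lags per octave and pairwise rebinning (exactly the direct estimator
at the first 16 lags); zero-lag point excluded everywhere; segments too dark
to define the estimator at a lag contribute nothing at that lag; fits use
bounded Levenberg–Marquardt with deterministic data-driven initialization
(amplitude from the first lag, $t_D$ from the half-amplitude lag, offset
from the tail mean) and $1/SE^2$ weights when the curve carries a
segment-to-segment dispersion; non-convergence is flagged on the result,
never thrown.

## Problem sizes used in the shipped validation

The test-suite and acceptance experiments are sized for a desk run: the
segment-bias experiment uses 500 segments of $T_{\rm seg} = 100\,t_D$
(25 s of trace at 20 µs bins, $D = 20\ \mu m^2/s$), averaged over 10
simulations in the acceptance script; the two-region recovery runs 20
simulated orbits (one 16.5 s orbit each across $D = 20/10\ \mu m^2/s$ with
2:1 reference contrast) and recovers the ratio to a few percent; the
correlator oracle comparison averages 20 independent 8192-bin traces. Larger
acquisitions only improve the statistics; every experiment is a function
argument away from the published-scale settings.

## Known limitations

* Fitting models are 2D-lateral; absolute $D$ from a $w_z/w_0 = 4$ volume is
  biased upward unless the axial term is negligible — use ratios, or a large
  axial ratio, or calibrate against a reference measurement.
* No triplet/blinking photophysics, detector afterpulsing or dead time; the
  package expects afterpulse-filtered traces.
* The full model assumes immobile, unsaturated binding sites and linearized
  kinetics; $N$ uses the package's amplitude convention.
* Threshold sorting is static in time; slowly moving region boundaries are
  only handled insofar as the interface band is discarded.
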