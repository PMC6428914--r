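# Acquisition-design calculator: segment-duration and scan-speed rules for
# slow-scanning, intensity-sorted FCS.

#' Minimum segment duration
#'
#' Segments shorter than about one hundred diffusion times visibly deform the
#' short-sequence ACF (shorter apparent t_D, negative offset, inflated
#' amplitude); at T_seg = 100 t_D the meaningful parameters t_D and G(0)
#' deviate by less than 5% from their long-acquisition values. The lower
#' limit returned is therefore 100 * t_D.
#'
#' @param t_D Diffusion time (s), > 0. Vectorized.
#' @return Minimum T_seg (s).
#' @export
min_segment_duration <- function(t_D) {
  if (any(t_D <= 0)) stop("t_D must be > 0")
  100 * t_D
}

#' Maximum scan speed for segment-based sorting FCS
#'
#' Beam motion is negligible over a segment when both
#' `v << w0 / T_seg` (the beam stays within a waist during one segment) and
#' `v^2 << w0^2 / (t_D * T_seg)` (scan-induced decorrelation slower than
#' diffusion). With the rule T_seg = 100 t_D the second (binding) bound
#' becomes exactly `0.4 * D / w0`, which is the design rule quoted for this
#' kind of acquisition. Both sub-bounds are always reported; the returned
#' `bound` is the design-rule bound `0.4 D / w0` when `T_seg = "rule"`, and
#' the minimum of the two sub-bounds when an explicit T_seg is given. The
#' "much less than" is *not* applied for you: `v_recommended` reports the
#' bound divided by the stated safety margin (default 10).
#'
#' @param D Diffusion coefficient (um^2/s), > 0.
#' @param w0 Lateral waist (um), > 0.
#' @param T_seg Segment duration (s), or `"rule"` for 100 t_D.
#' @param margin Safety factor used for `v_recommended`.
#' @return List: `bound` (um/s), `segment_bound` = w0/T_seg,
#'   `binding_bound` = sqrt(w0^2/(t_D T_seg)), `T_seg`, `margin`,
#'   `v_recommended` = bound/margin.
#' @export
max_scan_speed <- function(D, w0, T_seg = "rule", margin = 10) {
  if (D <= 0 || w0 <= 0) stop("D and w0 must be > 0")
  t_d <- td_from_diffusion(D, w0)
  rule <- identical(T_seg, "rule")
  if (rule) T_seg <- min_segment_duration(t_d)
  if (!is.numeric(T_seg) || T_seg <= 0) stop("T_seg must be > 0 or 'rule'")
  segment_bound <- w0 / T_seg
  binding_bound <- sqrt(w0^2 / (t_d * T_seg))
  bound <- if (rule) binding_bound else min(segment_bound, binding_bound)
  list(bound = bound, segment_bound = segment_bound,
       binding_bound = binding_bound, T_seg = T_seg, margin = margin,
       v_recommended = bound / margin)
}

#' Convert between scan speed, orbit frequency and period
#'
#' For a circular orbit of given diameter: v = pi * diameter * f,
#' period = 1/f. Give exactly one of `v`, `f`, `period`.
#'
#' @param v Scan speed (um/s).
#' @param f Orbit frequency (Hz).
#' @param period Orbit period (s).
#' @param orbit_diameter Orbit diameter (um), > 0.
#' @return List with all three of `v`, `f`, `period`.
#' @export
speed_frequency_convert <- function(v = NULL, f = NULL, period = NULL,
                                    orbit_diameter) {
  if (orbit_diameter <= 0) stop("orbit_diameter must be > 0")
  given <- !c(is.null(v), is.null(f), is.null(period))
  if (sum(given) != 1L) stop("give exactly one of v, f, period")
  circ <- pi * orbit_diameter
  if (!is.null(v)) {
    if (v < 0) stop("v must be >= 0")
    f <- v / circ
    period <- if (f > 0) 1 / f else Inf
  } else if (!is.null(f)) {
    if (f < 0) stop("f must be >= 0")
    v <- f * circ
    period <- if (f > 0) 1 / f else Inf
  } else {
    if (period <= 0) stop("period must be > 0")
    f <- 1 / period
    v <- f * circ
  }
  list(v = v, f = f, period = period)
}

#' Minimum line frequency of conventional scanning FCS
#'
#' A conventional scanning-FCS acquisition (correlating between successive
#' passes of the same position) must revisit each position faster than the
#' correlation decays, i.e. run at a line frequency above 1/t_D. This is the
#' quantity to contrast with the *orbit* frequencies used here, which sit
#' orders of magnitude below it.
#'
#' @param t_D Diffusion time (s), > 0. Vectorized.
#' @return Minimum frequency (Hz).
#' @export
conventional_scanfcs_min_frequency <- function(t_D) {
  if (any(t_D <= 0)) stop("t_D must be > 0")
  1 / t_D
}

#' Acquisition-design report
#'
#' @param D Expected diffusion coefficient (um^2/s).
#' @param w0 Lateral waist (um).
#' @param orbit_diameter Orbit diameter (um).
#' @return List with t_D, T_seg_min, the scan-speed bounds, the corresponding
#'   orbit-frequency bound, and the conventional scanning-FCS minimum
#'   frequency; printed nicely.
#' @export
design_report <- function(D, w0, orbit_diameter = 3) {
  t_d <- td_from_diffusion(D, w0)
  speed <- max_scan_speed(D, w0, "rule")
  conv <- speed_frequency_convert(v = speed$bound,
                                  orbit_diameter = orbit_diameter)
  out <- list(D = D, w0 = w0, orbit_diameter = orbit_diameter, t_D = t_d,
              T_seg_min = min_segment_duration(t_d),
              v_bound = speed$bound, segment_bound = speed$segment_bound,
              binding_bound = speed$binding_bound,
              v_recommended = speed$v_recommended,
              f_bound = conv$f, period_bound = conv$period,
              conventional_f_min = conventional_scanfcs_min_frequency(t_d))
  class(out) <- "design_report"
  out
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("Acquisition design for D = %g um^2/s, w0 = %g um, orbit diameter = %g um\n",
              x$D, x$w0, x$orbit_diameter))
  cat(sprintf("  t_D = w0^2/4D            = %.4g s\n", x$t_D))
  cat(sprintf("  T_seg lower limit        = %.4g s (100 t_D)\n", x$T_seg_min))
  cat(sprintf("  scan speed bound v <<    = %.4g um/s (0.4 D/w0; segment bound %.4g, binding bound %.4g)\n",
              x$v_bound, x$segment_bound, x$binding_bound))
  cat(sprintf("  recommended v (x%g margin) = %.4g um/s\n", 10,
              x$v_recommended))
  cat(sprintf("  orbit frequency f <<     = %.4g Hz (period >> %.4g s)\n",
              x$f_bound, x$period_bound))
  cat(sprintf("  conventional scanning FCS would need f > %.4g Hz\n",
              x$conventional_f_min))
  invisible(x)
}
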