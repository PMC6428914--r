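#' Scan geometry of an FCS acquisition
#'
#' Describes the observation volume and the (optional) slow circular orbit a
#' measurement was acquired with. Lengths are in micrometres, times in
#' seconds.
#'
#' @param orbit_radius Orbit radius R (um). Zero for a parked (static) beam.
#' @param orbit_period Orbit period T (s). Required when `scan_enabled`.
#' @param waist_lateral Lateral e^-2 waist w0 of the observation volume (um).
#' @param waist_axial Axial e^-2 waist wz (um); must be >= `waist_lateral`
#'   (the models assume an elongated volume, wz >> w0).
#' @param scan_enabled Logical; whether the beam moves. Defaults to
#'   `orbit_radius > 0`.
#'
#' @return An object of class `scan_geometry`.
#' @seealso [scan_speed()]
#' @export
scan_geometry <- function(orbit_radius = 0, orbit_period = NA_real_,
                          waist_lateral = 0.2, waist_axial = 4 * waist_lateral,
                          scan_enabled = orbit_radius > 0) {
  stopifnot(is.numeric(orbit_radius), length(orbit_radius) == 1L,
            is.numeric(waist_lateral), length(waist_lateral) == 1L,
            is.numeric(waist_axial), length(waist_axial) == 1L)
  if (orbit_radius < 0) stop("orbit_radius must be >= 0")
  if (waist_lateral <= 0) stop("waist_lateral must be > 0")
  if (waist_axial < waist_lateral)
    stop("waist_axial must be >= waist_lateral (elongated observation volume)")
  if (isTRUE(scan_enabled) && (!is.finite(orbit_period) || orbit_period <= 0))
    stop("orbit_period must be > 0 when scanning is enabled")
  structure(list(orbit_radius = orbit_radius,
                 orbit_period = as.numeric(orbit_period),
                 waist_lateral = waist_lateral,
                 waist_axial = waist_axial,
                 scan_enabled = isTRUE(scan_enabled)),
            class = "scan_geometry")
}

#' Scan speed of an orbital acquisition
#'
#' v = 2*pi*R/T for an enabled orbit; 0 for a parked beam.
#'
#' @param geometry A [scan_geometry()].
#' @return Scan speed in um/s.
#' @export
scan_speed <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (!geometry$scan_enabled) return(0)
  2 * pi * geometry$orbit_radius / geometry$orbit_period
}

#' @export
print.scan_geometry <- function(x, ...) {
  if (x$scan_enabled) {
    cat(sprintf("Orbital scan: R = %g um, T = %g s (v = %.4g um/s)\n",
                x$orbit_radius, x$orbit_period, scan_speed(x)))
  } else {
    cat("Static beam (no scan)\n")
  }
  cat(sprintf("Observation volume: w0 = %g um, wz = %g um\n",
              x$waist_lateral, x$waist_axial))
  invisible(x)
}

#' Binned photon-count intensity trace
#'
#' A uniformly binned multi-channel photon-count record, the raw input of all
#' downstream analysis. Counts are non-negative integers; all channels share
#' the bin time and length.
#'
#' @param counts Integer matrix (bins x channels), or a vector / list of
#'   equal-length vectors.
#' @param bin_time Bin width dt in seconds.
#' @param geometry A [scan_geometry()].
#' @param channel_names Character labels, e.g. `c("probe", "reference")`.
#' @param origin `"measured"` or `"simulated"`.
#' @param seed Integer seed the trace was generated from, or `NULL`.
#'
#' @return An object of class `intensity_trace` with fields `counts`
#'   (integer matrix with named columns), `bin_time`, `geometry`, `origin`,
#'   `seed`.
#' @export
intensity_trace <- function(counts, bin_time, geometry = scan_geometry(),
                            channel_names = NULL,
                            origin = c("measured", "simulated"), seed = NULL) {
  origin <- match.arg(origin)
  if (is.list(counts) && !is.data.frame(counts))
    counts <- do.call(cbind, counts)
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1)
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L) stop("trace must contain at least one bin")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(channel_names)) {
    channel_names <- colnames(counts)
    if (is.null(channel_names))
      channel_names <- if (ncol(counts) == 2L) c("probe", "reference") else
        paste0("ch", seq_len(ncol(counts)))
  }
  if (length(channel_names) != ncol(counts))
    stop("channel_names length must match number of channels")
  colnames(counts) <- channel_names
  if (!is.numeric(bin_time) || length(bin_time) != 1L || bin_time <= 0)
    stop("bin_time must be a positive scalar (seconds)")
  stopifnot(inherits(geometry, "scan_geometry"))
  structure(list(counts = counts, bin_time = bin_time, geometry = geometry,
                 origin = origin,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "intensity_trace")
}

#' Trace duration in seconds
#' @param trace An [intensity_trace()].
#' @return Duration = bins x bin_time (s).
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  nrow(trace$counts) * trace$bin_time
}

#' Channel names of a trace
#' @param trace An [intensity_trace()].
#' @return Character vector of channel labels.
#' @export
trace_channels <- function(trace) colnames(trace$counts)

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("Intensity trace (%s): %d bins x %d channel(s), dt = %g s, duration = %g s\n",
              x$origin, nrow(x$counts), ncol(x$counts), x$bin_time,
              trace_duration(x)))
  cat(sprintf("Channels: %s; mean rates: %s counts/s\n",
              paste(colnames(x$counts), collapse = ", "),
              paste(signif(colMeans(x$counts) / x$bin_time, 4), collapse = ", ")))
  print(x$geometry)
  invisible(x)
}

#' Correlation curve
#'
#' A fluctuation autocorrelation function G(tau) on a grid of positive lags.
#' The zero-lag (shot-noise) point is never part of a curve.
#'
#' @param lags Strictly increasing positive lag times (s).
#' @param values G(tau), dimensionless.
#' @param dispersion Per-lag standard error across contributing segments, or
#'   `NULL`. Present if and only if `n_averaged > 1`.
#' @param n_averaged Number of segment curves averaged into this one.
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, values, dispersion = NULL,
                              n_averaged = 1L) {
  lags <- as.numeric(lags); values <- as.numeric(values)
  if (length(lags) != length(values)) stop("lags and values lengths differ")
  if (length(lags) < 1L) stop("empty curve")
  if (any(lags <= 0)) stop("lags must be positive")
  if (any(diff(lags) <= 0)) stop("lags must be strictly increasing")
  n_averaged <- as.integer(n_averaged)
  if (n_averaged > 1L && is.null(dispersion))
    stop("dispersion required when n_averaged > 1")
  if (n_averaged <= 1L && !is.null(dispersion))
    stop("dispersion must be absent when n_averaged <= 1")
  if (!is.null(dispersion)) {
    dispersion <- as.numeric(dispersion)
    if (length(dispersion) != length(lags))
      stop("dispersion length must match lags")
  }
  structure(list(lags = lags, values = values, dispersion = dispersion,
                 n_averaged = n_averaged),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("Correlation curve: %d lags in [%.3g, %.3g] s, G(first lag) = %.4g, n_averaged = %d\n",
              length(x$lags), min(x$lags), max(x$lags), x$values[1],
              x$n_averaged))
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(lag = x$lags, G = x$values,
             SE = if (is.null(x$dispersion)) NA_real_ else x$dispersion,
             n_averaged = x$n_averaged)
}
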