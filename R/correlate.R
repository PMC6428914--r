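# Autocorrelation of whole traces and of short segments.

#' Fluctuation autocorrelation of a photon-count sequence
#'
#' Computes the normalized fluctuation autocorrelation
#' G(tau) = <dI(t) dI(t+tau)> / <I>^2 with *symmetric* normalization: at each
#' lag the means are taken over the two overlapping windows, which strongly
#' reduces the finite-length bias of short segments. The `"multi-tau"` scheme
#' evaluates `m` lags per octave with pairwise rebinning (quasi-log grid); the
#' `"direct"` scheme evaluates the same estimator at every integer lag and
#' serves as the oracle the multi-tau output can be checked against. The
#' zero-lag (shot-noise) point is excluded by construction.
#'
#' @param counts Integer/numeric vector of binned counts, or an
#'   [intensity_trace()] (then `channel` selects the column).
#' @param bin_time Bin width (s); taken from the trace if one is given.
#' @param scheme `"multi-tau"` or `"direct"`.
#' @param max_lag Largest lag to evaluate (s); must be smaller than the
#'   sequence duration. Default: a quarter of the duration.
#' @param m Multi-tau points per octave (default 8).
#' @param channel Channel name when `counts` is a trace.
#' @return A [correlation_curve()].
#' @export
autocorrelate <- function(counts, bin_time = NULL,
                          scheme = c("multi-tau", "direct"), max_lag = NULL,
                          m = 8L, channel = "probe") {
  scheme <- match.arg(scheme)
  if (inherits(counts, "intensity_trace")) {
    bin_time <- counts$bin_time
    counts <- counts$counts[, channel]
  }
  x <- as.numeric(counts)
  if (length(x) < 2L) stop("sequence must contain at least 2 bins")
  if (is.null(bin_time) || bin_time <= 0) stop("bin_time must be > 0")
  if (mean(x) == 0) stop("zero-mean trace: normalization undefined")
  duration <- length(x) * bin_time
  if (is.null(max_lag)) max_lag <- duration / 4
  if (max_lag >= duration) stop("max_lag must be smaller than the duration")
  if (max_lag < bin_time) stop("max_lag must be at least one bin")
  max_bins <- floor(max_lag / bin_time + 1e-9)
  if (scheme == "direct") {
    lags <- seq_len(min(max_bins, length(x) - 1L))
    vals <- acf_direct_cpp(x, as.integer(lags))
    correlation_curve(lags * bin_time, vals)
  } else {
    res <- acf_multitau_cpp(x, as.integer(m), max_bins)
    correlation_curve(res$lags_bins * bin_time, res$values)
  }
}

#' The multi-tau lag grid (in bins) for a given sequence length
#'
#' Exposed so callers can verify that segments of equal length share one grid.
#' @param n_bins Sequence length in bins.
#' @param max_lag_bins Largest lag in bins.
#' @param m Points per octave.
#' @return Numeric vector of lags in bin units.
#' @export
multitau_grid <- function(n_bins, max_lag_bins, m = 8L) {
  acf_multitau_cpp(rep(1, n_bins) + (seq_len(n_bins) %% 2) * 0.5,
                   as.integer(m), max_lag_bins)$lags_bins
}

#' Divide a trace into equal short segments
#'
#' Contiguous, non-overlapping segments of duration `T_seg` (trailing
#' remainder dropped); per-segment mean intensity is recorded for every
#' channel and, optionally, a short-sequence ACF is computed on `acf_channel`.
#' All segment ACFs share one lag grid, so they can be averaged lag-by-lag.
#'
#' @param trace An [intensity_trace()].
#' @param T_seg Segment duration (s); at least 2 bins, at most the duration.
#' @param compute_acf Compute per-segment ACFs (default TRUE).
#' @param acf_channel Channel the ACFs are computed on.
#' @param max_lag Largest segment-ACF lag (s); default `T_seg/2` — long
#'   enough that a free-offset fit can resolve the baseline.
#' @param m Multi-tau points per octave.
#' @return A `segment_set`: fields `segment_duration`, `bins_per_segment`,
#'   `start_time`, `means` (segments x channels), `curves` (list or NULL),
#'   `labels` (NA until sorted), `bin_time`.
#' @export
segment_trace <- function(trace, T_seg, compute_acf = TRUE,
                          acf_channel = "probe", max_lag = NULL, m = 8L) {
  stopifnot(inherits(trace, "intensity_trace"))
  dt <- trace$bin_time
  dur <- trace_duration(trace)
  if (T_seg < 2 * dt) stop("T_seg must be at least two bins")
  if (T_seg > dur * (1 + 1e-9)) stop("T_seg exceeds the trace duration")
  bins_per_seg <- as.integer(floor(T_seg / dt + 1e-9))
  n_seg <- as.integer(min(floor(dur / T_seg + 1e-9),
                          nrow(trace$counts) %/% bins_per_seg))
  if (is.null(max_lag)) max_lag <- bins_per_seg * dt / 2
  max_lag <- min(max_lag, (bins_per_seg - 1L) * dt)
  used <- seq_len(n_seg * bins_per_seg)
  means <- sapply(trace_channels(trace), function(ch)
    block_means_cpp(as.numeric(trace$counts[used, ch]), bins_per_seg, n_seg))
  means <- matrix(means, nrow = n_seg,
                  dimnames = list(NULL, trace_channels(trace)))
  curves <- NULL
  if (compute_acf) {
    xs <- as.numeric(trace$counts[used, acf_channel])
    max_bins <- floor(max_lag / dt + 1e-9)
    curves <- lapply(seq_len(n_seg), function(i) {
      seg <- xs[((i - 1L) * bins_per_seg + 1L):(i * bins_per_seg)]
      if (mean(seg) == 0) return(NULL)  # dark segment: no ACF
      res <- acf_multitau_cpp(seg, as.integer(m), max_bins)
      correlation_curve(res$lags_bins * dt, res$values)
    })
  }
  structure(list(segment_duration = bins_per_seg * dt,
                 requested_T_seg = T_seg,
                 bins_per_segment = bins_per_seg,
                 start_time = (seq_len(n_seg) - 1L) * bins_per_seg * dt,
                 means = means, curves = curves,
                 labels = rep(NA_character_, n_seg),
                 acf_channel = if (compute_acf) acf_channel else NA_character_,
                 bin_time = dt),
            class = "segment_set")
}

#' Number of segments in a segment set
#' @param segments A `segment_set`.
#' @return Integer count.
#' @export
n_segments <- function(segments) {
  stopifnot(inherits(segments, "segment_set"))
  nrow(segments$means)
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("Segment set: %d segments of %g s (%d bins each)%s\n",
              n_segments(x), x$segment_duration, x$bins_per_segment,
              if (is.null(x$curves)) "" else
                sprintf(", ACFs on '%s'", x$acf_channel)))
  if (!all(is.na(x$labels))) {
    cat("Labels:\n"); print(table(x$labels, useNA = "ifany"))
  }
  invisible(x)
}

#' Average correlation curves sharing one lag grid
#'
#' Unweighted per-lag mean; the dispersion is the per-lag standard error
#' across curves. A single curve is returned unchanged. Segments too dark to
#' define the estimator at a lag contribute `NaN` there; such entries are
#' excluded lag-by-lag, and a lag with fewer than two finite contributions is
#' dropped from the averaged curve.
#'
#' @param curves List of [correlation_curve()] objects on identical lag grids.
#' @return A [correlation_curve()] with `n_averaged = length(curves)`.
#' @export
average_curves <- function(curves) {
  curves <- Filter(Negate(is.null), curves)
  if (length(curves) < 1L) stop("no curves to average")
  stopifnot(all(vapply(curves, inherits, TRUE, "correlation_curve")))
  lags <- curves[[1]]$lags
  for (cv in curves)
    if (length(cv$lags) != length(lags) || any(cv$lags != lags))
      stop("curves must share an identical lag grid")
  if (length(curves) == 1L) return(curves[[1]])
  vals <- vapply(curves, `[[`, numeric(length(lags)), "values")
  vals <- matrix(vals, nrow = length(lags))
  fin <- is.finite(vals)
  n_fin <- rowSums(fin)
  mean_l <- rowSums(ifelse(fin, vals, 0)) / n_fin
  sd_l <- vapply(seq_along(lags), function(i)
    stats::sd(vals[i, fin[i, ]]), 0)
  keep <- n_fin >= 2L
  if (!any(keep)) stop("no lag has two finite contributions")
  correlation_curve(lags[keep], mean_l[keep],
                    dispersion = (sd_l / sqrt(n_fin))[keep],
                    n_averaged = length(curves))
}

#' Segment-length bias of short-sequence ACFs
#'
#' Quantifies how finite segment duration deforms segment-averaged ACFs in a
#' static-beam, single-region simulation. For each ratio T_seg/t_D the trace
#' is cut into segments of T_seg = ratio * t_D, the per-segment ACFs are
#' averaged and fitted with the short-sequence model (free offset b_s), and
#' the result is compared against the full-trace ACF fitted with the
#' one-component model (offset fixed to 0) *on the identical lag grid*, so the
#' reported deviations isolate the segmentation effect from lag-window
#' effects. Deviations are signed and relative: (segment fit - full fit) /
#' full fit.
#'
#' @param ratios Values of T_seg/t_D to scan.
#' @param base_config A static-beam single-region [sim_config()]; one
#'   simulation per seed is reused across all ratios.
#' @param seeds Integer vector of seeds (replicates).
#' @return Data frame with one row per ratio x seed: `ratio`, `seed`,
#'   `dev_G0`, `dev_tD` (signed relative deviations), `b_s` (fitted
#'   short-sequence offset), `n_segments`.
#' @export
segment_bias_scan <- function(ratios, base_config, seeds = 1L) {
  stopifnot(inherits(base_config, "sim_config"))
  g <- base_config$geometry
  if (g$scan_enabled) stop("bias scan requires a static beam")
  if (length(base_config$map) != 1L)
    stop("bias scan requires a single uniform region")
  D <- base_config$map[[1]]$D
  t_d <- g$waist_lateral^2 / (4 * D)
  out <- list()
  for (sd in seeds) {
    cfg <- base_config; cfg$seed <- as.integer(sd)
    trace <- simulate_trace(cfg)
    for (r in ratios) {
      T_seg <- r * t_d
      segs <- segment_trace(trace, T_seg)
      ss <- average_curves(segs$curves)
      full <- autocorrelate(trace, max_lag = max(ss$lags))
      # compare on the lags the two curves share (the segment grid is the
      # full-trace grid, minus any lag dropped as too dark)
      keep <- full$lags %in% ss$lags
      full_cut <- correlation_curve(full$lags[keep], full$values[keep])
      if (length(full_cut$lags) != length(ss$lags))
        stop("internal: segment and full-trace lag grids differ")
      fit_ss <- fit_curve(ss, "ss_1comp", w0 = g$waist_lateral)
      fit_full <- fit_curve(full_cut, "diff_1comp", w0 = g$waist_lateral)
      out[[length(out) + 1L]] <- data.frame(
        ratio = r, seed = sd,
        dev_G0 = fit_ss$parameters[["G0"]] / fit_full$parameters[["G0"]] - 1,
        dev_tD = fit_ss$parameters[["tD"]] / fit_full$parameters[["tD"]] - 1,
        b_s = fit_ss$parameters[["b"]],
        n_segments = n_segments(segs))
    }
  }
  do.call(rbind, out)
}
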