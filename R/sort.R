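# Detrend traces, sort segments into region populations by intensity
# thresholds, and emit per-population averaged ACFs.

#' Remove slow intensity drift from one channel of a trace
#'
#' Photobleaching (and other slow drifts) bias both the sorting thresholds and
#' the correlation amplitude, so the trace is detrended before segmentation.
#' `"moving-average-division"` rescales each bin by (global mean)/(local
#' moving average); `"single-exponential"` divides by a fitted
#' a*exp(-t/tau)+c normalized to its initial value and then rescales to the
#' global mean. Counts stay non-negative integers (rounded), the global mean
#' is preserved up to rounding, and the input trace is not modified.
#'
#' @param trace An [intensity_trace()].
#' @param channel Channel to detrend.
#' @param method `"moving-average-division"`, `"single-exponential"`, or
#'   `"none"`.
#' @param window Moving-average window (s). Should be much longer than the
#'   correlation lags of interest and at least 10 segment durations (checked
#'   by [sorted_acfs()]).
#' @return A new [intensity_trace()] with the channel detrended and a
#'   `detrend` field recording what was done.
#' @export
detrend <- function(trace, channel = "probe",
                    method = c("moving-average-division",
                               "single-exponential", "none"),
                    window = 5) {
  stopifnot(inherits(trace, "intensity_trace"))
  method <- match.arg(method)
  if (!channel %in% trace_channels(trace)) stop("unknown channel: ", channel)
  if (method == "none") return(trace)
  if (method == "moving-average-division" && trace$geometry$scan_enabled &&
      is.finite(trace$geometry$orbit_period) &&
      window < trace$geometry$orbit_period)
    warning("moving-average window shorter than the orbit period removes ",
            "genuine spatial contrast from a scanned trace", call. = FALSE)
  x <- as.numeric(trace$counts[, channel])
  n <- length(x)
  gm <- mean(x)
  if (gm == 0) stop("degenerate trace: channel is all zero")
  dt <- trace$bin_time

  if (method == "moving-average-division") {
    wbins <- max(3L, as.integer(round(window / dt)))
    if (wbins >= n) {
      local <- rep(gm, n)  # window spans the trace: nothing to remove
    } else {
      half <- wbins %/% 2L
      cs <- cumsum(c(0, x))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      local <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    if (any(local <= 0))
      stop("degenerate trace: local moving average reaches zero")
    y <- x * (gm / local)
  } else {
    # coarse profile for a cheap, robust exponential fit
    nb <- min(1000L, n)
    prof <- block_means_cpp(x[seq_len((n %/% nb) * nb)], n %/% nb, nb)
    tt <- (seq_len(nb) - 0.5) * (n %/% nb) * dt
    if (stats::sd(prof) < 1e-12 * max(gm, 1)) return(trace)  # no trend
    # fit only when a monotone head-to-tail trend is visible above the
    # profile noise; otherwise the trace is already trend-free
    k <- max(nb %/% 10L, 1L)
    head_m <- mean(prof[seq_len(k)])
    tail_m <- mean(prof[nb - seq_len(k) + 1L])
    if (abs(head_m - tail_m) < 3 * stats::sd(prof) / sqrt(k)) return(trace)
    a0 <- head_m - tail_m
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(prof ~ a * exp(-tt / tau) + c0,
                   start = list(a = a0, tau = max(tt) / 2, c0 = tail_m))),
      error = function(e) NULL)
    if (is.null(fit)) return(trace)  # trend not exponential-like; leave as is
    cf <- stats::coef(fit)
    if (!all(is.finite(cf)) || cf[["tau"]] <= 0) return(trace)
    t_all <- (seq_len(n) - 0.5) * dt
    f <- cf[["a"]] * exp(-t_all / cf[["tau"]]) + cf[["c0"]]
    f0 <- cf[["a"]] + cf[["c0"]]
    if (any(f <= 0) || f0 <= 0)
      stop("degenerate trace: fitted trend reaches zero")
    y <- x / (f / f0)
    y <- y * (gm / mean(y))
  }
  counts <- trace$counts
  counts[, channel] <- as.integer(pmax(round(y), 0))
  out <- trace
  out$counts <- counts
  out$detrend <- c(out$detrend,
                   list(list(channel = channel, method = method,
                             window = window)))
  out
}

#' A sorting rule: one population, one or more threshold clauses
#'
#' A segment belongs to the rule's population when *all* clauses hold
#' (logical AND). `below` means segment mean <= threshold, `above` means
#' mean > threshold, so two-sided rules with t_low < t_high leave the
#' interface band (t_low, t_high] unlabeled ("discarded"), which is how
#' mixed-behaviour boundary segments are excluded. Thresholds are absolute
#' segment-mean counts, or percentiles of the observed segment means when
#' `percentile` is given instead.
#'
#' @param population Population label.
#' @param ... Clauses built with [clause()].
#' @return A `sort_rule`.
#' @export
sort_rule <- function(population, ...) {
  clauses <- list(...)
  if (length(clauses) == 1L && is.list(clauses[[1]]) &&
      !inherits(clauses[[1]], "sort_clause")) clauses <- clauses[[1]]
  if (!length(clauses)) stop("a rule needs at least one clause")
  stopifnot(all(vapply(clauses, inherits, TRUE, "sort_clause")))
  structure(list(population = population, clauses = clauses),
            class = "sort_rule")
}

#' @rdname sort_rule
#' @param channel Channel whose segment mean is compared.
#' @param relation `"below"` (mean <= threshold) or `"above"`
#'   (mean > threshold).
#' @param threshold Absolute threshold (mean counts per bin), or `NULL`.
#' @param percentile Percentile (0-100) of the observed segment means used to
#'   set the threshold, or `NULL`. Exactly one of `threshold`/`percentile`.
#' @export
clause <- function(channel, relation = c("below", "above"), threshold = NULL,
                   percentile = NULL) {
  relation <- match.arg(relation)
  if (is.null(threshold) == is.null(percentile))
    stop("give exactly one of threshold or percentile")
  if (!is.null(threshold) && threshold < 0)
    stop("threshold must be non-negative")
  if (!is.null(percentile) && (percentile < 0 || percentile > 100))
    stop("percentile must be in [0, 100]")
  structure(list(channel = channel, relation = relation,
                 threshold = threshold, percentile = percentile),
            class = "sort_clause")
}

#' Default tercile rules on the reference channel
#'
#' "below" = 33rd percentile and "above" = 67th percentile of the segment
#' means, so the middle (interface) band is discarded.
#'
#' @param channel Reference channel name.
#' @param low,high Population labels.
#' @return List of two [sort_rule()]s.
#' @export
tercile_rules <- function(channel = "reference", low = "low", high = "high") {
  list(sort_rule(low, clause(channel, "below", percentile = 33)),
       sort_rule(high, clause(channel, "above", percentile = 67)))
}

.resolve_thresholds <- function(rules, segments) {
  means <- segments$means
  warned <- character()
  rules <- lapply(rules, function(rule) {
    rule$clauses <- lapply(rule$clauses, function(cl) {
      if (is.null(cl$threshold)) {
        v <- means[, cl$channel]
        cl$threshold <- unname(stats::quantile(v, cl$percentile / 100))
        # a percentile split is meaningless when the spread of segment means
        # is no larger than the shot noise of a homogeneous specimen
        noise <- sqrt(max(mean(v), 0) / segments$bins_per_segment)
        gap <- diff(stats::quantile(v, c(1, 2) / 3))
        if (gap <= 2 * noise && !(cl$channel %in% warned)) {
          warned <<- c(warned, cl$channel)
          warning("channel '", cl$channel, "' shows no usable contrast ",
                  "between segments (tercile gap within shot noise); ",
                  "percentile sorting is not meaningful", call. = FALSE)
        }
      }
      cl
    })
    rule
  })
  rules
}

#' Sort segments into populations by intensity thresholds
#'
#' Each segment is labeled with the population of the unique rule whose
#' clauses all hold; a segment matching no rule is labeled `"discarded"`. Two
#' rules matching the same segment is an error (overlapping rules), reported
#' with the offending segment indices: precedence would silently change
#' results between rule orderings.
#'
#' @param segments A `segment_set` from [segment_trace()].
#' @param rules List of [sort_rule()]s with unique population names.
#' @return The segment set with `labels` filled in, resolved thresholds in
#'   `attr(, "thresholds")`, and label counts in `attr(, "label_counts")`.
#' @export
apply_sort <- function(segments, rules) {
  stopifnot(inherits(segments, "segment_set"))
  if (inherits(rules, "sort_rule")) rules <- list(rules)
  stopifnot(all(vapply(rules, inherits, TRUE, "sort_rule")))
  pops <- vapply(rules, `[[`, "", "population")
  if (anyDuplicated(pops)) stop("population names must be unique")
  for (rule in rules)
    for (cl in rule$clauses)
      if (!cl$channel %in% colnames(segments$means))
        stop("rule references unknown channel: ", cl$channel)
  rules <- .resolve_thresholds(rules, segments)
  n <- n_segments(segments)
  match_mat <- vapply(rules, function(rule) {
    hit <- rep(TRUE, n)
    for (cl in rule$clauses) {
      v <- segments$means[, cl$channel]
      hit <- hit & if (cl$relation == "below") v <= cl$threshold
                   else v > cl$threshold
    }
    hit
  }, logical(n))
  match_mat <- matrix(match_mat, nrow = n)
  nm <- rowSums(match_mat)
  if (any(nm > 1L))
    stop("overlapping rules: segments ",
         paste(utils::head(which(nm > 1L), 10), collapse = ", "),
         if (sum(nm > 1L) > 10) " ..." else "",
         " match more than one rule")
  labels <- rep("discarded", n)
  for (j in seq_along(rules)) labels[match_mat[, j]] <- pops[j]
  segments$labels <- labels
  attr(segments, "thresholds") <- lapply(rules, function(rule)
    list(population = rule$population,
         clauses = lapply(rule$clauses, function(cl)
           cl[c("channel", "relation", "threshold")])))
  attr(segments, "label_counts") <- table(factor(labels,
                                                 levels = c(pops, "discarded")))
  segments
}

#' Audit table of a sorted segment set
#'
#' @param segments A labeled `segment_set`.
#' @return Data frame: index, start_time, per-channel means, label.
#' @export
label_audit <- function(segments) {
  stopifnot(inherits(segments, "segment_set"))
  d <- data.frame(index = seq_len(n_segments(segments)),
                  start_time = segments$start_time)
  for (ch in colnames(segments$means)) d[[paste0("mean_", ch)]] <-
      segments$means[, ch]
  d$label <- segments$labels
  d
}

#' Per-population averaged ACFs (the full sorting pipeline)
#'
#' detrend -> segment -> per-segment ACF -> label -> per-population average.
#' Sorting always uses the detrended trace; ACFs are computed on the probe
#' channel (detrended too when it appears in `detrend_channels`). Populations
#' that capture no segments are dropped with a warning. Conservation holds by
#' construction: population counts + discarded = total segments.
#'
#' @param trace An [intensity_trace()].
#' @param T_seg Segment duration (s).
#' @param rules List of [sort_rule()]s; default: tercile split on the
#'   reference channel.
#' @param detrend_method See [detrend()]; applied to every channel in
#'   `detrend_channels`. The default is the parametric single-exponential
#'   detrend: it removes a photobleaching-like decay while leaving the
#'   orbit-scale spatial structure of a scanned trace intact, which a
#'   moving average with a sub-orbit window would destroy.
#' @param detrend_window Window (s); default `max(10 * T_seg, 5)`. A window
#'   below 10 segment durations triggers a warning.
#' @param detrend_channels Channels to detrend before sorting/correlating.
#' @param acf_channel Channel the ACFs are computed on.
#' @param max_lag,m Passed to [segment_trace()].
#' @return Named list of [correlation_curve()]s, one per non-empty population,
#'   with the labeled `segment_set` in `attr(, "segments")`.
#' @export
sorted_acfs <- function(trace, T_seg, rules = tercile_rules(),
                        detrend_method = "single-exponential",
                        detrend_window = NULL,
                        detrend_channels = trace_channels(trace),
                        acf_channel = "probe", max_lag = NULL, m = 8L) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (is.null(detrend_window)) detrend_window <- max(10 * T_seg, 5)
  if (detrend_method != "none" && detrend_window < 10 * T_seg)
    warning("detrend window shorter than 10 segment durations: ",
            "the detrend may eat genuine slow fluctuations")
  work <- trace
  if (detrend_method != "none")
    for (ch in detrend_channels)
      work <- detrend(work, ch, detrend_method, detrend_window)
  segs <- segment_trace(work, T_seg, compute_acf = TRUE,
                        acf_channel = acf_channel, max_lag = max_lag, m = m)
  segs <- apply_sort(segs, rules)
  pops <- setdiff(unique(segs$labels), "discarded")
  pops <- pops[order(match(pops, vapply(
    if (inherits(rules, "sort_rule")) list(rules) else rules,
    `[[`, "", "population")))]
  out <- list()
  for (p in pops) {
    idx <- which(segs$labels == p)
    curves <- segs$curves[idx]
    curves <- Filter(Negate(is.null), curves)
    if (!length(curves)) {
      warning("population '", p, "' has no usable segments; dropped")
      next
    }
    out[[p]] <- average_curves(curves)
  }
  empty <- setdiff(vapply(if (inherits(rules, "sort_rule")) list(rules) else
    rules, `[[`, "", "population"), names(out))
  if (length(empty))
    warning("population(s) with no segments: ", paste(empty, collapse = ", "))
  attr(out, "segments") <- segs
  out
}
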