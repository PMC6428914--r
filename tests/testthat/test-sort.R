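test_that("detrending leaves trend-free traces essentially untouched", {
  tr <- flat_two_channel_trace(n = 20000, rate_probe = 50)
  for (m in c("moving-average-division", "single-exponential")) {
    out <- detrend(tr, "probe", m, window = 5)
    expect_lt(max(abs(out$counts[, "probe"] - tr$counts[, "probe"])), 2)
    expect_equal(mean(out$counts[, "probe"]), mean(tr$counts[, "probe"]),
                 tolerance = 1e-3)
    expect_identical(out$counts[, "reference"], tr$counts[, "reference"])
  }
  const <- intensity_trace(cbind(probe = rep(9L, 1000)), 1e-3)
  expect_identical(detrend(const, "probe", "moving-average-division", 0.2)$counts,
                   const$counts)
  expect_identical(detrend(const, "probe", "none")$counts, const$counts)
})

test_that("an exponential photobleaching trend is removed", {
  # post-detrend slope consistent with zero across seeds (regression oracle)
  tvals <- (seq_len(30000) - 0.5) * 1e-3
  tstats <- vapply(1:20, function(s) {
    set.seed(600 + s)
    lam <- 80 * exp(-tvals / 15)  # strong decay over a 30 s trace
    tr <- intensity_trace(cbind(probe = rpois(30000, lam)), 1e-3)
    out <- detrend(tr, "probe", "single-exponential")
    fit <- summary(stats::lm(as.numeric(out$counts[, "probe"]) ~ tvals))
    fit$coefficients["tvals", "t value"]
  }, 0)
  # per-seed t-statistics hover around 0; their mean sits within noise
  expect_gt(mean(abs(tstats) < 2), 0.8)
  expect_lt(abs(mean(tstats)) / (sd(tstats) / sqrt(length(tstats))), 4)
})

test_that("degenerate traces are refused", {
  z <- intensity_trace(cbind(probe = rep(0L, 100)), 1e-3)
  expect_error(detrend(z, "probe", "moving-average-division", 0.01),
               "all zero")
  spik <- intensity_trace(cbind(probe = c(rep(0L, 60), rep(10L, 40))), 1e-3)
  expect_error(detrend(spik, "probe", "moving-average-division", 0.005),
               "zero")
})

test_that("rules label segments exhaustively and conservatively", {
  tr <- flat_two_channel_trace(n = 6000, rate_probe = 5, rate_ref = 3)
  segs <- segment_trace(tr, 0.1, compute_acf = FALSE)
  n <- n_segments(segs)

  all_rule <- sort_rule("everything", clause("reference", "below", Inf))
  lab <- apply_sort(segs, list(all_rule))
  expect_true(all(lab$labels == "everything"))

  two <- list(sort_rule("lo", clause("reference", "below", percentile = 33)),
              sort_rule("hi", clause("reference", "above", percentile = 67)))
  # the flat fixture has no genuine contrast, so the degeneracy warning fires
  lab2 <- suppressWarnings(apply_sort(segs, two))
  counts <- attr(lab2, "label_counts")
  expect_equal(sum(counts), n)  # conservation
  expect_true(all(c("lo", "hi", "discarded") %in% names(counts)))
  expect_gt(counts[["discarded"]], 0)  # interface band exists
  thr <- attr(lab2, "thresholds")
  t_lo <- thr[[1]]$clauses[[1]]$threshold
  t_hi <- thr[[2]]$clauses[[1]]$threshold
  v <- segs$means[, "reference"]
  expect_true(all(lab2$labels[v <= t_lo] == "lo"))
  expect_true(all(lab2$labels[v > t_lo & v <= t_hi] == "discarded"))

  # order invariance for non-overlapping rules
  lab3 <- suppressWarnings(apply_sort(segs, rev(two)))
  expect_identical(lab3$labels, lab2$labels)
})

test_that("two-channel AND rules match a brute-force relabelling", {
  tr <- flat_two_channel_trace(n = 8000, rate_probe = 6, rate_ref = 4,
                               seed = 12)
  segs <- segment_trace(tr, 0.1, compute_acf = FALSE)
  rule <- sort_rule("bright", clause("probe", "above", 6),
                    clause("reference", "above", 4))
  lab <- apply_sort(segs, list(rule))
  manual <- segs$means[, "probe"] > 6 & segs$means[, "reference"] > 4
  expect_identical(lab$labels == "bright", unname(manual))
  expect_equal(sum(attr(lab, "label_counts")), n_segments(segs))
})

test_that("overlapping rules are an error naming the offending segments", {
  tr <- flat_two_channel_trace(n = 2000)
  segs <- segment_trace(tr, 0.1, compute_acf = FALSE)
  rules <- list(sort_rule("a", clause("reference", "below", Inf)),
                sort_rule("b", clause("probe", "below", Inf)))
  expect_error(apply_sort(segs, rules), "overlapping rules")
  expect_error(apply_sort(segs, list(sort_rule("a", clause("reference",
                                                           "below", 1)),
                                     sort_rule("a", clause("reference",
                                                           "above", 1)))),
               "unique")
  expect_error(apply_sort(segs, list(sort_rule("a", clause("nope", "below",
                                                           1)))),
               "unknown channel")
})

test_that("a contrast-free reference makes percentile sorting warn", {
  tr <- flat_two_channel_trace(n = 6000)
  segs <- segment_trace(tr, 0.1, compute_acf = FALSE)
  expect_warning(apply_sort(segs, tercile_rules()), "no usable contrast")
})

test_that("sorting everything into one population equals the plain average", {
  cfg <- uniform_static_preset(duration = 1.5, seed = 17)
  tr <- simulate_trace(cfg)
  rules <- list(sort_rule("all", clause("reference", "below", Inf)))
  sorted <- sorted_acfs(tr, 0.05, rules, detrend_method = "none")
  plain <- average_curves(segment_trace(tr, 0.05)$curves)
  expect_identical(sorted$all$values, plain$values)
  expect_identical(sorted$all$lags, plain$lags)
})

test_that("sorting fidelity does not degrade as contrast rises", {
  # ground truth from the beam position at each segment midpoint
  frac_correct <- vapply(c(1.2, 2, 5), function(ct) {
    cfg <- two_region_orbit_preset(contrast = ct, duration = 8.25,
                                   n_particles = 1, brightness = 0, seed = 23)
    tr <- simulate_trace(cfg)
    segs <- segment_trace(tr, 0.1, compute_acf = FALSE)
    labs <- apply_sort(segs, tercile_rules())$labels
    tmid <- segs$start_time + 0.05
    ang <- 2 * pi * tmid / cfg$geometry$orbit_period
    truth <- region_at(cfg$map, cfg$geometry$orbit_radius * cos(ang),
                       cfg$geometry$orbit_radius * sin(ang))
    used <- labs != "discarded"
    mean((labs == "high")[used] == (truth == "high")[used])
  }, 0)
  expect_true(all(diff(frac_correct) >= 0))
  expect_gt(frac_correct[2], 0.95)
})

test_that("bleached traces recover the input D after detrending", {
  rules <- list(sort_rule("all", clause("reference", "below", Inf)))
  d_of <- function(cfg, method) {
    tr <- simulate_trace(cfg)
    cv <- sorted_acfs(tr, 0.05, rules, detrend_method = method)$all
    fit_curve(cv, "ss_1comp", w0 = 0.2)$derived$D
  }
  res <- t(vapply(1:3, function(i) {
    base <- uniform_static_preset(duration = 3, n_particles = 60,
                                  seed = 700 + i)
    bl <- base; bl$bleach_rate <- 60
    c(ref = d_of(base, "none"), fix = d_of(bl, "single-exponential"))
  }, c(ref = 0, fix = 0)))
  # detrended bleached estimates sit inside the no-bleach replicate interval
  spread <- sd(res[, "ref"]) + sd(res[, "fix"])
  expect_lt(abs(mean(res[, "fix"]) - mean(res[, "ref"])),
            2 * spread + 0.1 * mean(res[, "ref"]))
})

test_that("detrending restores stationary segment means under bleaching", {
  cfg <- uniform_static_preset(duration = 3, n_particles = 60, seed = 29)
  cfg$bleach_rate <- 100  # signal decays several-fold but keeps a baseline
  tr <- simulate_trace(cfg)
  means_of <- function(t) segment_trace(t, 0.05,
                                        compute_acf = FALSE)$means[, "probe"]
  raw <- means_of(tr)
  fixed <- means_of(detrend(tr, "probe", "single-exponential"))
  idx <- seq_along(raw)
  expect_lt(cor(raw, idx), -0.5)            # strong decay before
  expect_lt(abs(cor(fixed, idx)), 0.25)     # near-stationary after
  expect_equal(mean(fixed), mean(raw), tolerance = 0.05)  # mean preserved
})
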