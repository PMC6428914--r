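test_that("a constant trace has zero correlation at every lag", {
  x <- rep(7L, 512)
  for (scheme in c("multi-tau", "direct")) {
    cc <- autocorrelate(x, 1e-3, scheme = scheme, max_lag = 0.1)
    expect_true(all(cc$values == 0))
    expect_gte(min(cc$lags), 1e-3)  # zero lag excluded by construction
  }
})

test_that("multi-tau agrees with the direct estimator on shared lags", {
  x <- ar1_poisson_counts(n = 8192, tau_bins = 60)
  mt <- autocorrelate(x, 1e-3, "multi-tau", max_lag = 0.24)
  di <- autocorrelate(x, 1e-3, "direct", max_lag = 0.24)
  idx <- match(mt$lags, di$lags)
  expect_false(anyNA(idx))
  # level-0 lags (1..16 bins) evaluate the identical estimator
  lev0 <- mt$lags <= 16e-3
  expect_identical(mt$values[lev0], di$values[idx][lev0])
  # on a single trace the two estimators agree to within 1% of the
  # amplitude at every shared lag (the curve itself is noisy at deep lags,
  # so pointwise relative deviation is only meaningful after averaging;
  # see the acceptance suite for the replicate-averaged comparison)
  amp <- di$values[1]
  expect_lt(max(abs(mt$values - di$values[idx])), 0.01 * amp)
})

test_that("shuffling a trace destroys its correlation", {
  x <- ar1_poisson_counts(n = 8192, tau_bins = 150)
  set.seed(5)
  xs <- sample(x)
  cc <- autocorrelate(xs, 1e-3, "multi-tau", max_lag = 0.4)
  # i.i.d. counts: G should be within counting noise of zero at every lag
  expect_lt(max(abs(cc$values)), 0.02)
  orig <- autocorrelate(x, 1e-3, "multi-tau", max_lag = 0.4)
  expect_gt(orig$values[1], 0.1)  # the unshuffled trace is correlated
})

test_that("autocorrelate rejects degenerate inputs", {
  expect_error(autocorrelate(rep(0L, 100), 1e-3, max_lag = 0.01), "zero-mean")
  expect_error(autocorrelate(c(1L, 2L), 1e-3, max_lag = 1e-3), NA)
  expect_error(autocorrelate(1L, 1e-3), "at least 2")
  expect_error(autocorrelate(rep(1L, 10), 1e-3, max_lag = 0.5), "duration")
})

test_that("segment counts follow floor(duration / T_seg)", {
  mk <- function(n, dt) intensity_trace(
    matrix(rep(1L, 2 * n), ncol = 2, dimnames = list(NULL, NULL)),
    dt, channel_names = c("probe", "reference"))
  tr <- mk(132000, 1e-3)          # 132 s at 1 ms bins
  expect_equal(n_segments(segment_trace(tr, 0.131, compute_acf = FALSE)), 1007L)
  tr2 <- mk(26400, 1e-2)          # 264 s at 10 ms bins
  expect_equal(n_segments(segment_trace(tr2, 1.05, compute_acf = FALSE)), 251L)
  tr3 <- mk(1000, 1e-3)
  expect_equal(n_segments(segment_trace(tr3, 1.0, compute_acf = FALSE)), 1L)
  expect_error(segment_trace(tr3, 2.0), "duration")
  expect_error(segment_trace(tr3, 1e-3), "two bins")
})

test_that("per-segment means average exactly to the covered-span mean", {
  tr <- flat_two_channel_trace(n = 4096)
  segs <- segment_trace(tr, 0.1, compute_acf = FALSE)  # 100-bin segments
  used <- seq_len(n_segments(segs) * segs$bins_per_segment)
  for (ch in trace_channels(tr))
    expect_equal(mean(segs$means[, ch]), mean(tr$counts[used, ch]))
})

test_that("segment ACFs share one lag grid and average as expected", {
  tr <- flat_two_channel_trace(n = 6000)
  segs <- segment_trace(tr, 0.5)
  grids <- lapply(Filter(Negate(is.null), segs$curves), `[[`, "lags")
  expect_true(all(vapply(grids, identical, TRUE, grids[[1]])))

  lags <- grids[[1]]
  c0 <- correlation_curve(lags, rep(0, length(lags)))
  c2 <- correlation_curve(lags, rep(0.2, length(lags)))
  avg <- average_curves(list(c0, c2))
  expect_equal(avg$values, rep(0.1, length(lags)))
  expect_equal(avg$dispersion, rep(0.1, length(lags)))
  expect_equal(avg$n_averaged, 2L)
  one <- average_curves(list(c2))
  expect_identical(one, c2)
  expect_error(average_curves(list(c0, correlation_curve(lags[-1], lags[-1]))),
               "identical lag grid")
})

test_that("the standard error of averaged curves shrinks as 1/sqrt(N)", {
  set.seed(11)
  lags <- (1:20) * 1e-3
  base <- 0.2 / (1 + lags / 5e-3)
  mk <- function() correlation_curve(lags, base + rnorm(20, 0, 0.05))
  ses <- vapply(c(16, 64, 256), function(N)
    mean(average_curves(replicate(N, mk(), simplify = FALSE))$dispersion), 0)
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.25)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.25)
})

test_that("free-diffusion transit times match w0^2/(4D) (quasi-2D volume)", {
  # elongated axial waist so the lateral-only model applies; several seeds
  fitted <- vapply(1:8, function(i) {
    cfg <- uniform_static_preset(D = 20, w0 = 0.2, wz = 8, box = c(2, 2, 32),
                                 duration = 2.5, seed = 300 + i)
    tr <- simulate_trace(cfg)
    ac <- autocorrelate(tr, max_lag = 6e-3)
    fit_curve(ac, "diff_1comp", w0 = 0.2)$parameters[["tD"]]
  }, 0)
  t_true <- td_from_diffusion(20, 0.2)
  se <- sd(fitted) / sqrt(length(fitted))
  expect_lt(abs(mean(fitted) - t_true), 3 * se + 0.02 * t_true)
})

test_that("short segments deform the ssACF the way theory predicts", {
  # shorter apparent transit time, negative offset, inflated amplitude
  cfg <- uniform_static_preset(duration = 6, seed = 42)
  tab <- segment_bias_scan(c(10, 400), cfg, seeds = 42)
  r10 <- tab[tab$ratio == 10, ]
  expect_lt(r10$dev_tD, 0)       # apparent t_D shortened
  expect_lt(r10$b_s, 0)          # negative baseline offset
  expect_gt(r10$dev_G0, 0)       # slightly inflated amplitude
  r400 <- tab[tab$ratio == 400, ]
  # far above the lower limit the deformation collapses
  expect_lt(abs(r400$dev_tD), abs(r10$dev_tD))
  expect_lt(max(abs(r400$dev_tD), abs(r400$dev_G0)), 0.06)
})
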