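test_that("closed-form model values are exact", {
  # one-component: G0 (1 + t/tD)^-1
  expect_equal(eval_model("diff_1comp", c(G0 = 0.1, tD = 1e-3, b = 0), 1e-3),
               0.05)
  # doubling tD halves D and vice versa
  expect_equal(diffusion_from_td(5e-4, 0.2), 20)
  expect_equal(diffusion_from_td(1e-3, 0.2), 10)
  expect_equal(diffusion_from_td(2.45e-4, 0.14), 20)
  expect_error(diffusion_from_td(0, 0.2), "> 0")
  expect_error(eval_model("diff_1comp", c(G0 = 0.1, tD = -1), 1e-3), "tD")
})

test_that("the scanned models collapse to pure diffusion at v = 0", {
  lags <- 10^seq(-5, 0, length.out = 200)
  ref <- eval_model("diff_1comp", c(G0 = 0.3, tD = 5e-4, b = 0), lags)
  full <- eval_model("scan_diff", c(G0 = 0.3, tD = 5e-4, R = 1.5, v = 0),
                     lags, w0 = 0.2)
  appr <- eval_model("scan_diff_approx", c(G0 = 0.3, tD = 5e-4, v = 0),
                     lags, w0 = 0.2)
  expect_identical(full, ref)
  expect_identical(appr, ref)
})

test_that("the slow-scan approximation matches the full scanned model", {
  # small-angle regime: v * T_seg <= 0.1 * w0
  w0 <- 0.2; T_seg <- 0.131; v <- 0.1 * w0 / T_seg; R <- 1.5
  lags <- seq(1e-5, T_seg, length.out = 400)
  p3 <- c(G0 = 0.3, tD = 5e-4, R = R, v = v)
  p4 <- c(G0 = 0.3, tD = 5e-4, v = v)
  g3 <- eval_model("scan_diff", p3, lags, w0 = w0)
  g4 <- eval_model("scan_diff_approx", p4, lags, w0 = w0)
  expect_lt(max(abs(g4 / g3 - 1)), 0.01)
})

test_that("fits recover generating parameters on noiseless model data", {
  lags <- 10^seq(-4.7, -1, length.out = 120)
  truth <- c(G0 = 0.1, tD = 5e-4)
  cv <- correlation_curve(lags, eval_model("diff_1comp",
                                           c(truth, b = 0), lags))
  fit <- fit_curve(cv, "diff_1comp", w0 = 0.2)
  expect_equal(fit$parameters[["G0"]], 0.1, tolerance = 1e-6)
  expect_equal(fit$parameters[["tD"]], 5e-4, tolerance = 1e-6)
  expect_equal(fit$derived$D, 20, tolerance = 1e-5)
  expect_true(fit$converged)

  truth_ss <- c(G0 = 0.5, tD = 2e-3, b = -0.02)
  cv2 <- correlation_curve(lags, eval_model("ss_1comp", truth_ss, lags))
  fit2 <- fit_curve(cv2, "ss_1comp")
  expect_equal(unname(fit2$parameters[c("G0", "tD", "b")]),
               unname(truth_ss), tolerance = 1e-5)

  g <- scan_geometry(1.5, 16.7, 0.2, 0.8)
  p5 <- c(G0 = 0.2, tD = 5e-4, R = 1.5, v = scan_speed(g))
  cv3 <- correlation_curve(lags, eval_model("scan_diff", p5, lags, w0 = 0.2))
  fit3 <- fit_curve(cv3, "scan_diff", geometry = g)
  expect_equal(fit3$parameters[["tD"]], 5e-4, tolerance = 1e-6)
  expect_equal(fit3$parameters[["R"]], 1.5)  # fixed from geometry
})

test_that("the global two-component fit shares diffusion times", {
  w0 <- 0.2
  tDs <- td_from_diffusion(0.07, w0)   # slow component
  tDf <- td_from_diffusion(2.1, w0)    # fast component
  lags <- 10^seq(-4, 1.5, length.out = 150)
  amps <- list(c(0.06, 0.02), c(0.03, 0.05), c(0.04, 0.04))
  curves <- lapply(amps, function(a)
    correlation_curve(lags, eval_model(
      "diff_2comp", c(Gslow0 = a[1], tDslow = tDs,
                      Gfast0 = a[2], tDfast = tDf), lags)))
  names(curves) <- paste0("c", 1:3)
  res <- global_fit_2comp(curves, w0 = w0)
  expect_equal(res$shared$tDslow, tDs, tolerance = 1e-4)
  expect_equal(res$shared$tDfast, tDf, tolerance = 1e-4)
  expect_equal(res$shared$Dslow, 0.07, tolerance = 1e-3)
  expect_equal(res$shared$Dfast, 2.1, tolerance = 1e-3)
  sf <- vapply(res$per_curve, function(f) f$derived$SF, 0)
  expect_equal(unname(sf),
               vapply(amps, function(a) a[1] / sum(a), 0), tolerance = 1e-4)
  expect_equal(unname(sf[3]), 0.5, tolerance = 1e-4)
  expect_true(all(sf >= 0 & sf <= 1))

  # identical curves get identical amplitudes
  res2 <- global_fit_2comp(list(a = curves[[1]], b = curves[[1]]), w0 = w0)
  expect_equal(res2$per_curve$a$parameters, res2$per_curve$b$parameters)
})

test_that("the reaction-diffusion model has the right limits", {
  w0 <- 0.2; lags <- 10^seq(-4.5, 0.8, length.out = 80)
  # vanishing association: pure diffusion
  g_bind0 <- full_model_acf(lags, N = 10, D = 20, kon = 0, koff = 1, w0 = w0)
  g_diff <- eval_model("diff_1comp",
                       c(G0 = 0.1, tD = td_from_diffusion(20, w0), b = 0),
                       lags)
  expect_equal(g_bind0, g_diff, tolerance = 1e-10)

  # reaction-dominant regime (t_D << 1/koff): the tail decays at rate koff
  koff <- 1
  tail_lags <- seq(0.6, 2.4, length.out = 40)
  g_tail <- full_model_acf(tail_lags, N = 10, D = 20, kon = 1, koff = koff,
                           w0 = w0)
  rate <- -coef(lm(log(g_tail) ~ tail_lags))[["tail_lags"]]
  expect_equal(rate, koff, tolerance = 0.05)

  # quadrature is converged: doubling the node count changes nothing material
  g_hi <- full_model_acf(lags, N = 10, D = 2, kon = 0.5, koff = 1, w0 = w0,
                         n_quad = 800L)
  g_lo <- full_model_acf(lags, N = 10, D = 2, kon = 0.5, koff = 1, w0 = w0)
  expect_lt(max(abs(g_hi - g_lo)), 1e-10)
})

test_that("the full-model fit is self-consistent and labels shaky baselines", {
  w0 <- 0.2
  # N = 50, D = 2, BF = 0.4, RT = 1  =>  koff = 1, kon = koff*BF/(1-BF)
  kon <- 1 * 0.4 / 0.6
  lags <- 10^seq(-4.5, 1.2, length.out = 120)
  cv <- correlation_curve(lags, full_model_acf(lags, 50, 2, kon, 1, w0))
  fit <- fit_full_model(cv, w0 = w0)
  expect_equal(fit$parameters[["N"]], 50, tolerance = 1e-3)
  expect_equal(fit$parameters[["D"]], 2, tolerance = 1e-3)
  expect_equal(fit$derived$BF, 0.4, tolerance = 1e-3)
  expect_equal(fit$derived$RT, 1, tolerance = 1e-3)
  expect_false(fit$derived$qualitative)  # baseline resolved

  short <- correlation_curve(lags[lags <= 0.05],
                             full_model_acf(lags[lags <= 0.05], 50, 0.2,
                                            kon, 0.2, w0))
  fit2 <- suppressWarnings(fit_full_model(short, w0 = w0))
  expect_true(fit2$derived$qualitative)
})

test_that("through-origin ratio slopes follow the closed form", {
  x <- c(10, 15, 20, 28)
  exact <- ratio_slope(cbind(x, 0.5 * x))
  expect_equal(exact$slope, 0.5)
  expect_equal(exact$slope_se, 0)
  single <- ratio_slope(matrix(c(20, 10), ncol = 2))
  expect_equal(single$slope, 0.5)
  expect_true(is.na(single$slope_se))
  set.seed(3)
  y <- 0.8 * x + rnorm(4, 0, 0.5)
  est <- ratio_slope(cbind(x, y))
  expect_equal(est$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
  expect_error(ratio_slope(cbind(x, -y)), "positive")

  exps <- list(cbind(x, 0.5 * x), cbind(x, 0.6 * x))
  multi <- ratio_slope(exps)
  expect_equal(multi$per_experiment_slopes, c(0.5, 0.6))
  expect_equal(multi$mean_of_slopes, 0.55)
})

test_that("spot-variation flags free diffusion from the D vs w^2 line", {
  flat <- data.frame(w_eff = c(0.140, 0.130, 0.115), D = c(20, 20, 20))
  res <- spot_variation(flat)
  expect_equal(res$slope, 0)
  expect_true(res$free_diffusion_consistent)

  rising <- data.frame(w_eff = c(0.10, 0.14, 0.20, 0.25))
  rising$D <- 5 + 100 * rising$w_eff^2
  res2 <- spot_variation(rising)
  expect_equal(res2$slope, 100, tolerance = 1e-9)
  expect_equal(res2$intercept, 5, tolerance = 1e-9)
  expect_error(spot_variation(data.frame(w_eff = c(0.1, 0.1), D = c(1, 2))),
               "distinct")
})

test_that("simulated free diffusion stays spot-variation consistent", {
  # three STED-like waists; the apparent D is scale-free for free diffusion
  waists <- c(0.140, 0.130, 0.115)
  ok <- vapply(1:12, function(i) {
    pts <- do.call(rbind, lapply(seq_along(waists), function(j) {
      w <- waists[j]
      cfg <- uniform_static_preset(D = 20, w0 = w, wz = 8, duration = 0.8,
                                   n_particles = 45,
                                   box = c(2, 2, 32), seed = 800 + 10 * i + j)
      tr <- simulate_trace(cfg)
      ac <- autocorrelate(tr, max_lag = 5e-3)
      data.frame(w_eff = w, D = fit_curve(ac, "diff_1comp",
                                          w0 = w)$derived$D)
    }))
    spot_variation(pts)$free_diffusion_consistent
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})
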