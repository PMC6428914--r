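# Fit models and derived statistics. All models are 2D-lateral (no axial
# term): the elongated observation volume (wz >> w0) makes the axial
# contribution slow and small, and the printed closed forms below carry no
# axial factor.
#
# Model ids:
#   ss_1comp    G(t) = G0 (1 + t/tD)^-1 + b      (short-sequence fit, b free)
#   diff_1comp  G(t) = G0 (1 + t/tD)^-1 + b      (b fixed to 0 by default)
#   scan_diff   G(t) = G0 (1+t/tD)^-1 exp(-(4R^2/w0^2) sin^2(v t/2R)/(1+t/tD))
#   scan_diff_approx  slow-scan small-angle form, sin x ~ x:
#               G(t) = G0 (1+t/tD)^-1 exp(-(v^2 t^2/w0^2)/(1+t/tD))
#   diff_2comp  G(t) = Gslow0 (1+t/tDslow)^-1 + Gfast0 (1+t/tDfast)^-1
#   full_model  reaction-diffusion (one diffusing + one transiently bound
#               population), evaluated by radial spatial-frequency quadrature.

#' Convert a diffusion time to a diffusion coefficient
#'
#' t_D = w0^2 / (4 D) for the lateral e^-2 waist w0, hence D = w0^2/(4 t_D).
#'
#' @param t_D Diffusion (transit) time (s), > 0. Vectorized.
#' @param w0 Lateral waist (um), > 0.
#' @return D in um^2/s.
#' @export
diffusion_from_td <- function(t_D, w0) {
  if (any(t_D <= 0) || any(w0 <= 0)) stop("t_D and w0 must be > 0")
  w0^2 / (4 * t_D)
}

#' @rdname diffusion_from_td
#' @param D Diffusion coefficient (um^2/s), > 0.
#' @export
td_from_diffusion <- function(D, w0) {
  if (any(D <= 0) || any(w0 <= 0)) stop("D and w0 must be > 0")
  w0^2 / (4 * D)
}

.model_param_names <- function(model_id) {
  switch(model_id,
         ss_1comp = c("G0", "tD", "b"),
         diff_1comp = c("G0", "tD", "b"),
         scan_diff = c("G0", "tD", "R", "v"),
         scan_diff_approx = c("G0", "tD", "v"),
         diff_2comp = c("Gslow0", "tDslow", "Gfast0", "tDfast"),
         full_model = c("N", "D", "kon", "koff"),
         stop("unknown model id: ", model_id))
}

#' Evaluate a correlation model on a lag grid
#'
#' Closed-form evaluation for the diffusion models; numerical quadrature for
#' the reaction-diffusion full model (see [full_model_acf()]).
#'
#' @param model_id One of `ss_1comp`, `diff_1comp`, `scan_diff`,
#'   `scan_diff_approx`, `diff_2comp`, `full_model`.
#' @param parameters Named numeric vector/list; see the model table above.
#'   `full_model` additionally needs `w0` here or via the `w0` argument.
#' @param lags Lag times (s).
#' @param w0 Lateral waist (um), used by `full_model`.
#' @return Numeric vector of model values G(lags).
#' @export
eval_model <- function(model_id, parameters, lags, w0 = NULL) {
  p <- as.list(parameters)
  t <- as.numeric(lags)
  need <- setdiff(.model_param_names(model_id),
                  c(names(p), if (model_id %in% c("ss_1comp", "diff_1comp")) "b"))
  if (length(need)) stop("missing parameters: ", paste(need, collapse = ", "))
  switch(model_id,
    ss_1comp = ,
    diff_1comp = {
      if (p$tD <= 0) stop("tD must be > 0")
      b <- if (is.null(p$b)) 0 else p$b
      p$G0 / (1 + t / p$tD) + b
    },
    scan_diff = {
      if (p$tD <= 0) stop("tD must be > 0")
      if (is.null(w0)) stop("scan_diff needs w0")
      s <- if (p$R > 0) sin(p$v * t / (2 * p$R))^2 else 0 * t
      p$G0 / (1 + t / p$tD) * exp(-(4 * p$R^2 / w0^2) * s / (1 + t / p$tD))
    },
    scan_diff_approx = {
      if (p$tD <= 0) stop("tD must be > 0")
      if (is.null(w0)) stop("scan_diff_approx needs w0")
      p$G0 / (1 + t / p$tD) * exp(-(p$v^2 * t^2 / w0^2) / (1 + t / p$tD))
    },
    diff_2comp = {
      if (p$tDslow <= 0 || p$tDfast <= 0) stop("diffusion times must be > 0")
      p$Gslow0 / (1 + t / p$tDslow) + p$Gfast0 / (1 + t / p$tDfast)
    },
    full_model = {
      if (is.null(w0)) w0 <- p$w0
      if (is.null(w0)) stop("full_model needs w0")
      full_model_acf(t, N = p$N, D = p$D, kon = p$kon, koff = p$koff, w0 = w0)
    })
}

#' Reaction-diffusion ("full model") correlation function
#'
#' One population diffuses freely with coefficient `D`; molecules bind to
#' immobile sites with pseudo-first-order association rate `kon` (written
#' k*_on, absorbing the free-site concentration) and dissociate with rate
#' `koff`. Both free and bound molecules fluoresce. Linearizing the kinetics,
#' each radial spatial frequency q relaxes through the two eigenmodes of
#'   M(q) = \[\[-(D q^2 + kon), koff\], \[kon, -koff\]\],
#' and the correlation is the detection-profile-weighted integral over q of
#' 1' exp(M t) p with p = (F_eq, B_eq). With the substitution u = q w0/2 the
#' pure-diffusion limit integrates exactly to (1 + t/tD)^-1, so the quadrature
#' (Gauss-Legendre on u in \[0, 6\]) is exact in that limit to ~1e-14.
#' Amplitude convention: G(0) = 1/N, with N the mean number of molecules in
#' the 2D observation area (no gamma factor applied).
#'
#' @param lags Lag times (s).
#' @param N Mean molecule number (amplitude 1/N).
#' @param D Free diffusion coefficient (um^2/s).
#' @param kon Pseudo-first-order association rate k*_on (1/s), >= 0.
#' @param koff Dissociation rate (1/s), > 0.
#' @param w0 Lateral waist (um).
#' @param n_quad Number of Gauss-Legendre nodes (default 200).
#' @return Numeric vector G(lags). Derived: BF = kon/(kon+koff),
#'   RT = 1/koff.
#' @export
full_model_acf <- function(lags, N, D, kon, koff, w0, n_quad = 200L) {
  if (N <= 0 || D <= 0 || koff <= 0 || kon < 0 || w0 <= 0)
    stop("full_model domain error: need N, D, koff, w0 > 0 and kon >= 0")
  gl <- pracma::gaussLegendre(n_quad, 0, 6)
  u <- gl$x; wq <- gl$w
  q2 <- (2 * u / w0)^2                   # q^2
  Feq <- koff / (kon + koff); Beq <- 1 - Feq
  w_int <- wq * 2 * u * exp(-u^2)        # integral weight: 2 u e^{-u^2} du
  vapply(as.numeric(lags), function(t) {
    a <- D * q2 + kon
    tr <- -(a + koff)
    disc <- sqrt(pmax((a - koff)^2 + 4 * kon * koff, 0))
    l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
    phi0p <- -D * q2 * Feq               # dPhi/dt at 0 (detected total)
    A <- ifelse(disc > 1e-12 * abs(tr) + 1e-300,
                (phi0p - l2) / (l1 - l2), 1)
    phi <- A * exp(l1 * t) + (1 - A) * exp(l2 * t)
    sum(w_int * phi) / N
  }, 0)
}

.curve_weights <- function(curve) {
  se <- curve$dispersion
  if (is.null(se)) return(NULL)
  pos <- se[se > 0]
  if (!length(pos)) return(NULL)
  se[se <= 0] <- min(pos)
  1 / se^2
}

.init_guess <- function(curve, model_id, w0) {
  g <- curve$values; l <- curve$lags
  G0 <- max(g[1], 1e-6)
  half <- which(g <= G0 / 2)
  tD <- if (length(half)) l[half[1]] else stats::median(l)
  tail_b <- mean(g[l >= stats::quantile(l, 0.9)], na.rm = TRUE)
  if (!is.finite(tail_b)) tail_b <- 0
  switch(model_id,
         ss_1comp = c(G0 = G0, tD = tD, b = tail_b),
         diff_1comp = c(G0 = G0, tD = tD, b = 0),
         scan_diff = c(G0 = G0, tD = tD),
         scan_diff_approx = c(G0 = G0, tD = tD),
         diff_2comp = c(Gslow0 = G0 / 2, tDslow = tD * 10,
                        Gfast0 = G0 / 2, tDfast = tD / 2),
         full_model = c(N = 1 / G0,
                        D = if (!is.null(w0)) diffusion_from_td(tD, w0) else 1,
                        kon = 1 / max(l), koff = 1 / max(l)))
}

.param_lower <- function(names) {
  lo <- stats::setNames(rep(0, length(names)), names)
  lo[names %in% c("tD", "tDslow", "tDfast", "koff")] <- 1e-12
  lo[names == "N"] <- 1e-12
  lo[names == "D"] <- 1e-12
  lo[names == "b"] <- -Inf
  lo
}

#' Fit a correlation model to a curve
#'
#' Weighted (1/SE^2 when the curve carries a dispersion, else unweighted)
#' bounded Levenberg-Marquardt least squares with deterministic
#' initialization: G0 from the first lag, tD from the half-amplitude lag, b
#' from the tail mean. For `diff_1comp` the offset b is fixed to 0 unless
#' freed through `fixed`. Scan models take R and v from `geometry` and fix
#' them by default. Non-convergence is flagged on the result, not thrown.
#'
#' @param curve A [correlation_curve()].
#' @param model_id Model identifier (see [eval_model()]).
#' @param w0 Lateral waist (um); enables the derived D.
#' @param geometry Optional [scan_geometry()] supplying w0, R and v.
#' @param start Optional named numeric vector overriding the initialization.
#' @param fixed Named numeric vector of parameters to hold fixed.
#' @return An `fcs_fit` object: `model_id`, `parameters`, `stderr`, `derived`
#'   (D per component, SF/BF/RT where defined, waist used), `gof` (rss,
#'   reduced chi-square, n_lags), `converged`.
#' @export
fit_curve <- function(curve, model_id, w0 = NULL, geometry = NULL,
                      start = NULL, fixed = NULL) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (any(!is.finite(curve$values))) {
    ok <- is.finite(curve$values)
    curve <- correlation_curve(curve$lags[ok], curve$values[ok],
                               dispersion = if (!is.null(curve$dispersion))
                                 curve$dispersion[ok],
                               n_averaged = if (is.null(curve$dispersion)) 1L
                               else curve$n_averaged)
  }
  if (!is.null(geometry)) {
    if (is.null(w0)) w0 <- geometry$waist_lateral
    if (model_id %in% c("scan_diff", "scan_diff_approx")) {
      sv <- c(R = geometry$orbit_radius, v = scan_speed(geometry))
      sv <- sv[setdiff(names(sv), names(fixed))]
      if (model_id == "scan_diff_approx") sv <- sv[names(sv) != "R"]
      fixed <- c(fixed, sv)
    }
  }
  if (model_id == "diff_1comp" && !("b" %in% names(c(start, fixed))))
    fixed <- c(fixed, c(b = 0))
  pnames <- .model_param_names(model_id)
  fixed <- fixed[names(fixed) %in% pnames]
  free_names <- setdiff(pnames, names(fixed))
  init <- .init_guess(curve, model_id, w0)
  if (!is.null(start)) init[names(start)] <- start
  init <- init[free_names]
  if (length(curve$lags) < 2 * length(free_names))
    stop("need at least 2 lags per free parameter")
  wts <- .curve_weights(curve)
  sw <- if (is.null(wts)) rep(1, length(curve$lags)) else sqrt(wts)
  resid_fn <- function(par) {
    p <- c(as.list(par), as.list(fixed))
    sw * (eval_model(model_id, p, curve$lags, w0 = w0) - curve$values)
  }
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fn,
                            lower = .param_lower(free_names)[free_names],
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  est <- stats::setNames(as.numeric(fit$par), free_names)
  params <- c(est, fixed)[pnames]
  dof <- max(length(curve$lags) - length(free_names), 1L)
  rss <- sum(fit$fvec^2)
  covm <- tryCatch(rss / dof * solve(fit$hessian), error = function(e) NULL)
  se <- stats::setNames(rep(NA_real_, length(free_names)), free_names)
  if (!is.null(covm)) {
    dg <- diag(covm); dg[dg < 0] <- NA
    se[] <- sqrt(dg)
  }
  converged <- fit$info %in% 1:4
  new_fcs_fit(model_id, params, se, curve, w0, rss, dof, converged)
}

new_fcs_fit <- function(model_id, params, se, curve, w0, rss, dof, converged) {
  derived <- list(w0 = w0)
  if (!is.null(w0)) {
    if (model_id %in% c("ss_1comp", "diff_1comp", "scan_diff",
                        "scan_diff_approx"))
      derived$D <- diffusion_from_td(params[["tD"]], w0)
    if (model_id == "diff_2comp") {
      derived$Dslow <- diffusion_from_td(params[["tDslow"]], w0)
      derived$Dfast <- diffusion_from_td(params[["tDfast"]], w0)
    }
  }
  if (model_id == "diff_2comp")
    derived$SF <- params[["Gslow0"]] / (params[["Gslow0"]] + params[["Gfast0"]])
  if (model_id == "full_model") {
    derived$BF <- params[["kon"]] / (params[["kon"]] + params[["koff"]])
    derived$RT <- 1 / params[["koff"]]
    derived$tD <- if (!is.null(w0)) td_from_diffusion(params[["D"]], w0)
    # a curve that has not decayed to baseline supports only qualitative reads
    derived$qualitative <- curve$values[length(curve$values)] >
      0.1 * curve$values[1]
  }
  structure(list(model_id = model_id, parameters = params, stderr = se,
                 derived = derived,
                 gof = list(rss = rss, red_chisq = rss / dof,
                            n_lags = length(curve$lags)),
                 converged = converged),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS fit: model %s%s\n", x$model_id,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (nm in names(x$parameters)) {
    se <- x$stderr[nm]
    cat(sprintf("  %-8s = %.6g%s\n", nm, x$parameters[[nm]],
                if (!is.na(se)) sprintf(" +/- %.3g", se) else ""))
  }
  d <- x$derived[!vapply(x$derived, is.null, TRUE)]
  for (nm in setdiff(names(d), "w0"))
    cat(sprintf("  %-8s : %s\n", nm, paste(signif(unlist(d[[nm]]), 6),
                                           collapse = " ")))
  cat(sprintf("  rss = %.4g, reduced chi^2 = %.4g over %d lags\n",
              x$gof$rss, x$gof$red_chisq, x$gof$n_lags))
  invisible(x)
}

#' Global two-component fit with shared diffusion times
#'
#' Fits every curve with the two-component diffusion model while sharing
#' tDslow and tDfast across all curves and letting the four amplitudes vary
#' per curve; this is the standard way to stabilise two-component fits across
#' measurements from one experiment. The slow fraction
#' SF = Gslow0/(Gslow0+Gfast0) is reported per curve.
#'
#' @param curves Named list of [correlation_curve()] (>= 2, or 1 with a
#'   warning).
#' @param w0 Lateral waist (um) for the derived Dslow/Dfast.
#' @param start Optional named start values `tDslow`, `tDfast`.
#' @return List with `shared` (tDslow, tDfast, their SEs, Dslow, Dfast,
#'   `degenerate` flag when they are within a factor 2), and `per_curve`:
#'   one `fcs_fit` per input curve.
#' @export
global_fit_2comp <- function(curves, w0 = NULL, start = NULL) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "correlation_curve")))
  if (length(curves) < 2L)
    warning("global fit over a single curve: shared times are per-curve times")
  k <- length(curves)
  init1 <- .init_guess(curves[[1]], "diff_2comp", w0)
  tDs <- c(tDslow = unname(init1["tDslow"]), tDfast = unname(init1["tDfast"]))
  if (!is.null(start)) tDs[names(start)] <- start
  amps <- unlist(lapply(curves, function(cv)
    .init_guess(cv, "diff_2comp", w0)[c("Gslow0", "Gfast0")]))
  par0 <- c(tDs, amps)  # names: tDslow, tDfast, then Gslow0/Gfast0 per curve
  sws <- lapply(curves, function(cv) {
    w <- .curve_weights(cv)
    if (is.null(w)) rep(1, length(cv$lags)) else sqrt(w)
  })
  resid_fn <- function(par) {
    unlist(lapply(seq_len(k), function(i) {
      p <- list(tDslow = par[[1]], tDfast = par[[2]],
                Gslow0 = par[[2 * i + 1]], Gfast0 = par[[2 * i + 2]])
      sws[[i]] * (eval_model("diff_2comp", p, curves[[i]]$lags) -
                    curves[[i]]$values)
    }))
  }
  lower <- c(1e-12, 1e-12, rep(0, 2 * k))
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn, lower = lower,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 400, ftol = 1e-12, ptol = 1e-12))
  par <- as.numeric(fit$par)
  # enforce slow/fast ordering
  swap <- par[1] < par[2]
  tDslow <- if (swap) par[2] else par[1]
  tDfast <- if (swap) par[1] else par[2]
  n_tot <- sum(vapply(curves, function(cv) length(cv$lags), 0L))
  dof <- max(n_tot - length(par), 1L)
  rss <- sum(fit$fvec^2)
  covm <- tryCatch(rss / dof * solve(fit$hessian), error = function(e) NULL)
  se12 <- if (!is.null(covm)) sqrt(pmax(diag(covm)[1:2], 0)) else c(NA, NA)
  degenerate <- tDslow < 2 * tDfast
  if (degenerate)
    warning("shared diffusion times within a factor 2: components poorly separated")
  per_curve <- lapply(seq_len(k), function(i) {
    a <- par[c(2 * i + 1, 2 * i + 2)]
    gs <- if (swap) a[2] else a[1]
    gf <- if (swap) a[1] else a[2]
    params <- c(Gslow0 = gs, tDslow = tDslow, Gfast0 = gf, tDfast = tDfast)
    res <- eval_model("diff_2comp", params, curves[[i]]$lags) -
      curves[[i]]$values
    new_fcs_fit("diff_2comp", params,
                stats::setNames(rep(NA_real_, 4), names(params)),
                curves[[i]], w0, sum(res^2),
                max(length(curves[[i]]$lags) - 4L, 1L),
                fit$info %in% 1:4)
  })
  names(per_curve) <- names(curves)
  shared <- list(tDslow = tDslow, tDfast = tDfast,
                 tDslow_se = if (swap) se12[2] else se12[1],
                 tDfast_se = if (swap) se12[1] else se12[2],
                 degenerate = degenerate, converged = fit$info %in% 1:4)
  if (!is.null(w0)) {
    shared$Dslow <- diffusion_from_td(tDslow, w0)
    shared$Dfast <- diffusion_from_td(tDfast, w0)
  }
  list(shared = shared, per_curve = per_curve)
}

#' Fit the reaction-diffusion full model
#'
#' @param curve A [correlation_curve()]; should span several decades of lag
#'   (a warning is emitted below 3).
#' @param w0 Lateral waist (um).
#' @param fixed Optional named vector of parameters to fix (of N, D, kon,
#'   koff).
#' @param start Optional named start values.
#' @return An `fcs_fit` with parameters N, D, kon, koff and derived BF, RT,
#'   tD, and a `qualitative` flag set when the curve lacks a resolved
#'   baseline.
#' @export
fit_full_model <- function(curve, w0, fixed = NULL, start = NULL) {
  span <- log10(max(curve$lags) / min(curve$lags))
  if (span < 3)
    warning(sprintf("lag span is %.2f decades; the full model is poorly constrained below 3", span))
  fit_curve(curve, "full_model", w0 = w0, fixed = fixed, start = start)
}

#' Through-origin ratio of paired diffusion coefficients
#'
#' Per-cell pairs (x, y) of diffusion coefficients measured in two regions of
#' the same cell; the per-experiment ratio y/x is the slope of the
#' least-squares line through the origin, slope = sum(x y)/sum(x^2), which
#' cancels cell-to-cell variability of the absolute values. With several
#' experiments the summary is the mean and SD of the per-experiment slopes.
#'
#' @param pairs Two-column data frame or matrix (x = denominator region,
#'   y = numerator region), or a list of such tables (one per independent
#'   experiment).
#' @return A `ratio_estimate`: `slope`, `slope_se`, `n_points` for the pooled
#'   fit, plus `per_experiment_slopes`, `mean_of_slopes`, `sd_of_slopes` when
#'   a list was given.
#' @export
ratio_slope <- function(pairs) {
  one <- function(tab) {
    tab <- as.matrix(tab)
    if (ncol(tab) != 2L) stop("pairs must have two columns (x, y)")
    if (any(!is.finite(tab)) || any(tab <= 0))
      stop("diffusion coefficients must be positive and finite")
    x <- tab[, 1]; y <- tab[, 2]
    slope <- sum(x * y) / sum(x^2)
    n <- length(x)
    # heteroscedasticity-robust (sandwich) standard error: per-cell D scatter
    # scales with the magnitude of D, so constant-variance residuals cannot
    # be assumed
    e <- y - slope * x
    se <- if (n >= 2)
      sqrt(n / (n - 1) * sum((x * e)^2)) / sum(x^2) else NA_real_
    list(slope = slope, slope_se = se, n_points = n)
  }
  if (is.list(pairs) && !is.data.frame(pairs) && !is.matrix(pairs)) {
    fits <- lapply(pairs, one)
    pooled <- one(do.call(rbind, lapply(pairs, as.matrix)))
    slopes <- vapply(fits, `[[`, 0, "slope")
    out <- c(pooled,
             list(per_experiment_slopes = slopes,
                  mean_of_slopes = mean(slopes),
                  sd_of_slopes = if (length(slopes) > 1) stats::sd(slopes)
                  else NA_real_))
  } else {
    out <- c(one(pairs),
             list(per_experiment_slopes = NULL, mean_of_slopes = NULL,
                  sd_of_slopes = NULL))
  }
  structure(out, class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("Through-origin ratio: slope = %.4g (SE %.3g, n = %d)\n",
              x$slope, x$slope_se, x$n_points))
  if (!is.null(x$per_experiment_slopes))
    cat(sprintf("  %d experiments: mean of slopes = %.4g, SD = %.3g\n",
                length(x$per_experiment_slopes), x$mean_of_slopes,
                x$sd_of_slopes))
  invisible(x)
}

#' Spot-variation (diffusion-law) summary
#'
#' Ordinary least squares of the apparent diffusion coefficient against the
#' squared effective waist. Free diffusion gives a flat line; a slope whose
#' confidence interval excludes zero indicates scale-dependent (hindered or
#' domain-confined) mobility.
#'
#' @param points Data frame/matrix with columns `w_eff` (um) and `D`
#'   (um^2/s); at least two distinct waists.
#' @param level Confidence level for the slope interval (default 0.95).
#' @return List: `intercept`, `slope`, `slope_ci`, `free_diffusion_consistent`
#'   (TRUE when the CI contains 0), and the underlying `lm` fit.
#' @export
spot_variation <- function(points, level = 0.95) {
  tab <- as.data.frame(points)
  if (!all(c("w_eff", "D") %in% names(tab))) {
    if (ncol(tab) >= 2) names(tab)[1:2] <- c("w_eff", "D")
    else stop("points must have columns w_eff and D")
  }
  if (length(unique(tab$w_eff)) < 2L)
    stop("need at least two distinct waists")
  tab$w2 <- tab$w_eff^2
  fit <- stats::lm(D ~ w2, data = tab)
  cf <- stats::coef(fit)
  ci <- if (nrow(tab) > 2) suppressWarnings(stats::confint(fit, "w2", level))
        else matrix(c(-Inf, Inf), 1)
  # noiseless input: slope exact, CI degenerate
  if (any(!is.finite(ci))) ci <- matrix(rep(cf[["w2"]], 2), 1)
  if (isTRUE(all.equal(stats::sd(stats::resid(fit)), 0)) && nrow(tab) > 2)
    ci <- matrix(rep(cf[["w2"]], 2), 1)
  # numerical floor: a slope whose effect over the observed waist range is
  # nil compared to D counts as zero
  eps <- 1e-9 * mean(abs(tab$D)) / max(diff(range(tab$w2)), 1e-12)
  list(intercept = unname(cf[1]), slope = unname(cf[["w2"]]),
       slope_ci = as.numeric(ci),
       free_diffusion_consistent = ci[1] <= eps && ci[2] >= -eps,
       fit = fit)
}
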