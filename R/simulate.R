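# Brownian-dynamics generator of two-channel photon traces: molecules diffuse
# through a 3D-Gaussian observation volume that is either parked or scanned on
# a slow circular orbit across a spatially heterogeneous specimen.

#' Define a specimen region
#'
#' Regions tile the focal plane; each carries a diffusion coefficient, a probe
#' brightness scale and a reference-channel count rate (the quasi-static
#' marker, e.g. a DNA stain, used downstream for sorting). Regions are matched
#' in order (first predicate wins) and the last region of a map must be the
#' catch-all `shape = "rest"`, so every point belongs to exactly one region.
#'
#' @param name Region label.
#' @param D Diffusion coefficient (um^2/s), > 0.
#' @param shape `"rest"` (everywhere not claimed earlier), `"halfplane"`
#'   (points with `a*x + b*y >= c`), or `"disc"` (centre `(a, b)`, radius `c`).
#' @param a,b,c Shape parameters (um).
#' @param probe_scale Dimensionless brightness scale (>= 0) applied to the
#'   probe molecules while inside this region.
#' @param reference_rate Reference-channel count rate (counts/s) contributed
#'   by this region; the simulated reference signal is the PSF-weighted blend
#'   of the region rates at the beam position (the reference marker is imaged
#'   through the same observation volume, so boundaries appear
#'   error-function-smooth, not as sharp steps).
#' @return A `sim_region` object.
#' @export
sim_region <- function(name, D, shape = c("rest", "halfplane", "disc"),
                       a = 0, b = 0, c = 0, probe_scale = 1,
                       reference_rate = 5e4) {
  shape <- match.arg(shape)
  if (!is.numeric(D) || D <= 0) stop("D must be > 0")
  if (probe_scale < 0) stop("probe_scale must be >= 0")
  if (reference_rate < 0) stop("reference_rate must be >= 0")
  structure(list(name = name, D = D, shape = shape, a = a, b = b, c = c,
                 probe_scale = probe_scale, reference_rate = reference_rate),
            class = "sim_region")
}

#' Assemble a region map
#'
#' @param ... `sim_region` objects, tested in order; the last must have
#'   `shape = "rest"` so the regions partition the plane.
#' @return A `region_map` object.
#' @export
region_map <- function(...) {
  regs <- list(...)
  if (length(regs) == 1L && is.list(regs[[1]]) &&
      !inherits(regs[[1]], "sim_region")) regs <- regs[[1]]
  stopifnot(length(regs) >= 1L,
            all(vapply(regs, inherits, TRUE, "sim_region")))
  if (regs[[length(regs)]]$shape != "rest")
    stop("last region must be the catch-all (shape = 'rest') so regions ",
         "partition the plane")
  nms <- vapply(regs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("region names must be unique")
  structure(regs, class = "region_map")
}

#' Region of a point
#' @param map A [region_map()].
#' @param x,y Focal-plane coordinates (um).
#' @return Region name at each point (first-match order).
#' @export
region_at <- function(map, x, y) {
  stopifnot(inherits(map, "region_map"))
  out <- character(length(x))
  for (i in seq_along(x)) {
    for (r in map) {
      hit <- switch(r$shape,
                    rest = TRUE,
                    halfplane = r$a * x[i] + r$b * y[i] >= r$c,
                    disc = (x[i] - r$a)^2 + (y[i] - r$b)^2 <= r$c^2)
      if (hit) { out[i] <- r$name; break }
    }
  }
  out
}

#' Simulation configuration
#'
#' Everything the Brownian-dynamics generator needs. The lateral box must be
#' at least 10 lateral waists and the axial box at least 4 axial waists, so
#' that periodic images of the observation volume do not overlap. Time
#' stepping is Euler-Maruyama with `step_substeps` sub-steps per bin; the
#' default keeps dt_sub <= t_D/100 for the fastest region (a warning is
#' emitted if a user-supplied value violates that guideline).
#'
#' @param n_particles Number of molecules.
#' @param map A [region_map()].
#' @param geometry A [scan_geometry()].
#' @param box Box side lengths (x, y, z) in um, periodic wrapping.
#' @param brightness Peak detected count rate per molecule at beam centre
#'   (counts/s).
#' @param background Background count rate (counts/s).
#' @param bin_time Bin width dt (s).
#' @param duration Trace duration (s).
#' @param bleach_rate Excitation-weighted bleaching rate (1/s), >= 0.
#' @param step_substeps Sub-steps per bin; `NULL` for the automatic rule.
#' @param seed Integer RNG seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_particles, map, geometry, box = c(4, 4, 4),
                       brightness = 1e5, background = 0, bin_time = 2e-5,
                       duration = 1, bleach_rate = 0, step_substeps = NULL,
                       seed = 1L) {
  stopifnot(inherits(map, "region_map"), inherits(geometry, "scan_geometry"))
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths")
  w0 <- geometry$waist_lateral; wz <- geometry$waist_axial
  if (box[1] < 10 * w0 || box[2] < 10 * w0)
    stop("lateral box must be >= 10 * waist_lateral")
  if (box[3] < 4 * wz) stop("axial box must be >= 4 * waist_axial")
  if (bin_time <= 0 || duration < bin_time)
    stop("need bin_time > 0 and duration >= bin_time")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  d_max <- max(vapply(map, `[[`, 0, "D"))
  t_d <- w0^2 / (4 * d_max)
  if (is.null(step_substeps))
    step_substeps <- max(1L, as.integer(ceiling(bin_time / (t_d / 100))))
  step_substeps <- as.integer(step_substeps)
  if (step_substeps < 1L) stop("step_substeps must be >= 1")
  if (bin_time / step_substeps > t_d / 100 * (1 + 1e-9))
    warning(sprintf(
      "sub-step %.3g s exceeds t_D/100 = %.3g s for the fastest region",
      bin_time / step_substeps, t_d / 100))
  structure(list(n_particles = as.integer(n_particles), map = map,
                 geometry = geometry, box = as.numeric(box),
                 brightness = brightness, background = background,
                 bin_time = bin_time, duration = duration,
                 bleach_rate = bleach_rate, step_substeps = step_substeps,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation: %d particles, box %s um, dt = %g s (%d substeps), duration = %g s, seed = %d\n",
              x$n_particles, paste(x$box, collapse = " x "), x$bin_time,
              x$step_substeps, x$duration, x$seed))
  for (r in x$map)
    cat(sprintf("  region '%s' (%s): D = %g um^2/s, probe scale %g, reference %g counts/s\n",
                r$name, r$shape, r$D, r$probe_scale, r$reference_rate))
  print(x$geometry)
  invisible(x)
}

.shape_code <- c(rest = 0L, halfplane = 1L, disc = 2L)

#' Simulate a two-channel photon-count trace
#'
#' Molecules take independent Gaussian steps with per-axis variance
#' 2 D dt_sub (D evaluated at the particle's current region, Ito convention)
#' in a periodic box, while the beam either sits at the origin or follows the
#' circular orbit. Probe counts per bin are Poisson with mean equal to the
#' integrated detection profile over the bin plus background; reference counts
#' are Poisson with the PSF-weighted blend of the region reference rates at
#' the beam position. Identical config and seed give bit-identical traces.
#'
#' @param config A [sim_config()].
#' @return An [intensity_trace()] with channels `probe` and `reference`.
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$geometry
  n_bins <- as.integer(floor(config$duration / config$bin_time + 1e-9))
  regs <- config$map
  set.seed(config$seed)
  counts <- sim_trace_cpp(
    config$n_particles, config$box,
    vapply(regs, function(r) .shape_code[[r$shape]], 0L),
    vapply(regs, `[[`, 0, "a"), vapply(regs, `[[`, 0, "b"),
    vapply(regs, `[[`, 0, "c"), vapply(regs, `[[`, 0, "D"),
    vapply(regs, `[[`, 0, "probe_scale"),
    vapply(regs, `[[`, 0, "reference_rate"),
    g$orbit_radius, if (g$scan_enabled) g$orbit_period else 1,
    g$scan_enabled, g$waist_lateral, g$waist_axial,
    config$brightness, config$background, config$bin_time, n_bins,
    config$step_substeps, config$bleach_rate)
  intensity_trace(counts, config$bin_time, g,
                  channel_names = c("probe", "reference"),
                  origin = "simulated", seed = config$seed)
}

#' Uniform-specimen static-beam preset
#'
#' Convenience configuration for calibration runs: one region, beam parked at
#' the origin. The defaults emulate a typical single-point FCS condition: the
#' smallest box the volume constraints allow (10 lateral waists by 4 axial
#' waists) and a particle number giving an amplitude G(0) of order 1 (about
#' one molecule in the observation volume) at a per-molecule brightness high
#' enough that shot noise does not dominate the segment statistics.
#'
#' @param D Diffusion coefficient (um^2/s).
#' @param w0,wz Waists (um).
#' @param n_particles,brightness,background,bin_time,duration,box,seed See
#'   [sim_config()].
#' @param reference_rate Reference-channel rate (counts/s).
#' @return A `sim_config`.
#' @export
uniform_static_preset <- function(D = 20, w0 = 0.2, wz = 0.8,
                                  n_particles = 90, brightness = 1e5,
                                  background = 0, bin_time = 2e-5,
                                  duration = 25, box = c(2, 2, 3.2),
                                  reference_rate = 5e4, seed = 1L) {
  sim_config(n_particles,
             region_map(sim_region("uniform", D, "rest",
                                   reference_rate = reference_rate)),
             scan_geometry(0, NA, w0, wz, scan_enabled = FALSE),
             box = box, brightness = brightness, background = background,
             bin_time = bin_time, duration = duration, seed = seed)
}

#' Two-region orbital-scan preset
#'
#' The classic validation scenario: a half-plane boundary at x = 0 splits the
#' specimen into a high-D region (x >= 0) and a low-D region (x < 0), and the
#' beam orbits the origin so exactly half the orbit lies in each region. The
#' reference channel differs between the regions by the stated contrast, which
#' is what the sorter keys on.
#'
#' The default geometry scans one orbit of radius 0.5 um in 16.5 s
#' (v ~ 0.19 um/s, far below the 0.4 D/w0 bound for either region) inside the
#' smallest box the volume constraints allow, with a particle number giving an
#' amplitude of order 1.
#'
#' @param D_high,D_low Diffusion coefficients (um^2/s) for the two regions.
#' @param contrast Reference-rate ratio high:low (e.g. 2 for 2:1).
#' @param geometry A [scan_geometry()] with scanning enabled.
#' @param reference_rate Low-region reference rate (counts/s).
#' @param n_particles,brightness,background,bin_time,duration,box,seed See
#'   [sim_config()].
#' @return A `sim_config`.
#' @export
two_region_orbit_preset <- function(D_high = 20, D_low = 10, contrast = 2,
                                    geometry = scan_geometry(0.5, 16.5, 0.2, 0.8),
                                    reference_rate = 5e4, n_particles = 60,
                                    brightness = 1e5, background = 0,
                                    bin_time = 2e-5, duration = 16.5,
                                    box = c(2, 2, 3.2), seed = 1L) {
  if (D_high <= 0 || D_low <= 0) stop("diffusion coefficients must be > 0")
  if (contrast <= 0) stop("contrast must be > 0")
  if (!geometry$scan_enabled) stop("preset requires an enabled orbit")
  map <- region_map(
    sim_region("high", D_high, "halfplane", a = 1, b = 0, c = 0,
               reference_rate = reference_rate * contrast),
    sim_region("low", D_low, "rest", reference_rate = reference_rate))
  sim_config(n_particles, map, geometry, box = box, brightness = brightness,
             background = background, bin_time = bin_time, duration = duration,
             seed = seed)
}

#' Expected mean detection profile over the box
#'
#' Numerical quadrature of the 3D-Gaussian detection profile over the periodic
#' box, used as an independent check of simulated count rates:
#' expected rate = background + n_particles * brightness * mean_W.
#'
#' @param config A [sim_config()] (single uniform region assumed for the
#'   brightness scale).
#' @return Mean of W(r) over the box (dimensionless).
#' @export
mean_profile_over_box <- function(config) {
  g <- config$geometry
  gauss_marginal <- function(L, w) {
    f <- function(u) exp(-2 * u^2 / w^2)
    stats::integrate(f, -L / 2, L / 2, rel.tol = 1e-10)$value / L
  }
  gauss_marginal(config$box[1], g$waist_lateral) *
    gauss_marginal(config$box[2], g$waist_lateral) *
    gauss_marginal(config$box[3], g$waist_axial)
}
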