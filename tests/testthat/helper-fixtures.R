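# Shared fixtures. Simulations are cached so several test files can reuse one
# Brownian-dynamics run; everything is generated in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# 6 s static-beam free-diffusion run (D = 20 um^2/s): used by the correlator,
# rate-oracle and bias-direction tests.
static_trace_6s <- function() cached("static6", {
  simulate_trace(uniform_static_preset(duration = 6, seed = 42))
})

# a cheap correlated photon trace with no Brownian dynamics: Poisson counts
# driven by a smooth AR(1) rate (correlation time ~tau_bins bins)
ar1_poisson_counts <- function(n = 8192, tau_bins = 150, base = 40,
                               rel_amp = 0.6, seed = 99) {
  set.seed(seed)
  rho <- exp(-1 / tau_bins)
  z <- as.numeric(stats::arima.sim(list(ar = rho), n, sd = sqrt(1 - rho^2)))
  lam <- base * pmax(1 + rel_amp * z, 0.05)
  stats::rpois(n, lam)
}

# two-channel Poisson trace with constant rates (no dynamics): cheap segment
# and sorting fixture
flat_two_channel_trace <- function(n = 4000, rate_probe = 5,
                                   rate_ref = 3, bin_time = 1e-3, seed = 7) {
  set.seed(seed)
  intensity_trace(cbind(stats::rpois(n, rate_probe), stats::rpois(n, rate_ref)),
                  bin_time, scan_geometry(waist_lateral = 0.2),
                  channel_names = c("probe", "reference"))
}
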