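#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Region lookup in the focal (x,y) plane. Regions are tested in order and the
// first matching predicate wins; the last region must be a catch-all
// (shape 0), so every point maps to exactly one region.
// shape codes: 0 = everywhere, 1 = half-plane a*x + b*y >= c, 2 = disc
// centre (a,b) radius c.
static inline int region_of(double x, double y, const int* shape,
                            const double* pa, const double* pb,
                            const double* pc, int nreg) {
  for (int r = 0; r < nreg; r++) {
    switch (shape[r]) {
    case 0: return r;
    case 1: if (pa[r] * x + pb[r] * y >= pc[r]) return r; break;
    case 2: {
      const double dx = x - pa[r], dy = y - pb[r];
      if (dx * dx + dy * dy <= pc[r] * pc[r]) return r;
      break;
    }
    default: ;
    }
  }
  return nreg - 1; // unreachable when last region is catch-all
}

static inline double wrap(double v, double half, double full) {
  while (v >= half) v -= full;
  while (v < -half) v += full;
  return v;
}

// Reference-channel rate at a beam position: the reference marker is imaged
// through the same observation profile, so each region contributes its rate
// weighted by the PSF mass lying inside it. The lateral profile
// exp(-2 d^2/w0^2) is a Gaussian with sd w0/2, so a half-plane boundary at
// signed distance d contributes Phi(d/(w0/2)) (error-function edge); a disc
// is treated radially the same way (adequate for radius >> w0). Regions are
// matched in order, each taking its share of the remaining PSF mass.
static inline double ref_rate_at(double x, double y, const int* shape,
                                 const double* pa, const double* pb,
                                 const double* pc, const double* ref,
                                 int nreg, double w0) {
  const double sd = w0 / 2.0;
  double remaining = 1.0, rate = 0.0;
  for (int r = 0; r < nreg; r++) {
    double f;
    switch (shape[r]) {
    case 1: {
      const double nrm = std::sqrt(pa[r] * pa[r] + pb[r] * pb[r]);
      const double d = (pa[r] * x + pb[r] * y - pc[r]) / (nrm > 0 ? nrm : 1);
      f = R::pnorm(d / sd, 0.0, 1.0, 1, 0);
      break;
    }
    case 2: {
      const double dx = x - pa[r], dy = y - pb[r];
      const double d = pc[r] - std::sqrt(dx * dx + dy * dy);
      f = R::pnorm(d / sd, 0.0, 1.0, 1, 0);
      break;
    }
    default: f = 1.0;
    }
    rate += ref[r] * f * remaining;
    remaining *= (1.0 - f);
    if (remaining <= 0) break;
  }
  return rate;
}

// Brownian-dynamics photon-trace generator.
//
// Particles take independent Gaussian steps with per-axis variance
// 2 * D(region at current position) * dt_sub (Ito convention: the step is
// drawn from the region the particle starts the step in), in a periodic box
// centred on the origin. The beam follows a circular orbit of radius R and
// period T in the focal plane (or sits at the origin when scanning is off).
// Detection profile W(r) = exp(-2(dx^2+dy^2)/w0^2 - 2 dz^2/wz^2) (e^-2
// waists). Probe counts per bin are Poisson with mean
//   background*dt + sum_substeps sum_particles brightness * scale(region) *
//                   W(r_p - r_beam) * dt_sub
// and the reference channel is Poisson with the PSF-weighted region rate at
// the beam position (mid-bin), emulating a quasi-static reference marker
// imaged through the same observation volume. Optional
// excitation-weighted bleaching kills a particle with per-substep survival
// probability exp(-bleach_rate * W * dt_sub).
//
// Uses R's RNG: fully reproducible after set.seed() in the caller.
// [[Rcpp::export]]
IntegerMatrix sim_trace_cpp(int n_particles, NumericVector box,
                            IntegerVector shape, NumericVector pa,
                            NumericVector pb, NumericVector pc,
                            NumericVector region_D, NumericVector region_scale,
                            NumericVector region_ref, double orbit_radius,
                            double orbit_period, bool scan_enabled, double w0,
                            double wz, double brightness, double background,
                            double dt, int n_bins, int substeps,
                            double bleach_rate) {
  RNGScope scope;
  const int nreg = shape.size();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double hx = Lx / 2, hy = Ly / 2, hz = Lz / 2;
  const double dt_sub = dt / substeps;
  const double iw2 = 2.0 / (w0 * w0), iz2 = 2.0 / (wz * wz);
  const double omega = scan_enabled ? 2.0 * M_PI / orbit_period : 0.0;

  std::vector<double> px(n_particles), py(n_particles), pz(n_particles);
  std::vector<double> sig(nreg);
  std::vector<char> alive(n_particles, 1);
  for (int r = 0; r < nreg; r++) sig[r] = std::sqrt(2.0 * region_D[r] * dt_sub);
  for (int p = 0; p < n_particles; p++) {
    px[p] = (unif_rand() - 0.5) * Lx;
    py[p] = (unif_rand() - 0.5) * Ly;
    pz[p] = (unif_rand() - 0.5) * Lz;
  }

  IntegerMatrix out(n_bins, 2);
  const double phot_sub = brightness * dt_sub;

  for (int i = 0; i < n_bins; i++) {
    double lam = background * dt;
    for (int s = 0; s < substeps; s++) {
      const double t = (i * (double)substeps + s + 0.5) * dt_sub;
      double bx = 0.0, by = 0.0;
      if (scan_enabled) {
        bx = orbit_radius * std::cos(omega * t);
        by = orbit_radius * std::sin(omega * t);
      }
      for (int p = 0; p < n_particles; p++) {
        const int reg = region_of(px[p], py[p], shape.begin(), pa.begin(),
                                  pb.begin(), pc.begin(), nreg);
        if (alive[p]) {
          const double dx = px[p] - bx, dy = py[p] - by, dz = pz[p];
          const double W =
              std::exp(-(dx * dx + dy * dy) * iw2 - dz * dz * iz2);
          lam += phot_sub * region_scale[reg] * W;
          if (bleach_rate > 0.0) {
            if (unif_rand() > std::exp(-bleach_rate * W * dt_sub))
              alive[p] = 0;
          }
        }
        const double sd = sig[reg];
        px[p] = wrap(px[p] + sd * norm_rand(), hx, Lx);
        py[p] = wrap(py[p] + sd * norm_rand(), hy, Ly);
        pz[p] = wrap(pz[p] + sd * norm_rand(), hz, Lz);
      }
    }
    out(i, 0) = (int)R::rpois(lam);
    const double tmid = (i + 0.5) * dt;
    double bx = 0.0, by = 0.0;
    if (scan_enabled) {
      bx = orbit_radius * std::cos(omega * tmid);
      by = orbit_radius * std::sin(omega * tmid);
    }
    const double rrate = ref_rate_at(bx, by, shape.begin(), pa.begin(),
                                     pb.begin(), pc.begin(),
                                     region_ref.begin(), nreg, w0);
    out(i, 1) = (int)R::rpois(rrate * dt);
  }
  return out;
}
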