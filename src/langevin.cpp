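#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rigid-body Langevin dynamics of a helical bead model near an implicit
// membrane, inside a funnel restraint. Degrees of freedom: axis-centre
// translation (x, y, z) and the roll angle phi about the helix long axis
// (kept parallel to the membrane plane). Units: kcal/mol, Angstrom, ps;
// masses are pre-converted to kcal mol^-1 ps^2 A^-2 on the R side.
//
// Bead i sits at axial offset x_off[i] with radial distance rad[i] and
// helical phase phase[i]; its height is z + rad[i] * cos(phi + phase[i]).
// Per-bead membrane well: U = -depth * exp(-(zb - center)^2 / (2 w^2))
// with a per-bead centre height (side-chain classes reach different depths
// into the head-group region),
// plus a harmonic repulsive core below z_core. The funnel wall acts on the
// axis centre. Integration is BAOAB; noise comes from R's RNG so that
// set.seed() gives bitwise-reproducible trajectories.

struct Params {
  int nb;
  const double *rad, *phase, *depth, *center;
  double w, k_core, z_core;
  bool membrane_on;
  bool funnel_on;
  double f_tana, f_rcyl, f_zcc, f_zmax, f_kwall; // f_zmax < 0 => no top wall
  bool trap_on;
  double k_trap, cx, cy, cz;
};

// Potential energy and gradient wrt (x, y, z, phi).
static double potential(const Params &p, double x, double y, double z,
                        double phi, double grad[4]) {
  double U = 0.0;
  grad[0] = grad[1] = grad[2] = grad[3] = 0.0;
  if (p.membrane_on) {
    for (int i = 0; i < p.nb; ++i) {
      double c = std::cos(phi + p.phase[i]);
      double s = std::sin(phi + p.phase[i]);
      double zb = z + p.rad[i] * c;
      double dzb_dphi = -p.rad[i] * s;
      double u = zb - p.center[i];
      double E = std::exp(-u * u / (2.0 * p.w * p.w));
      U += -p.depth[i] * E;
      double dU_dzb = p.depth[i] * E * u / (p.w * p.w);
      if (zb < p.z_core) {
        double d = p.z_core - zb;
        U += p.k_core * d * d;
        dU_dzb += -2.0 * p.k_core * d;
      }
      grad[2] += dU_dzb;
      grad[3] += dU_dzb * dzb_dphi;
    }
  }
  if (p.funnel_on) {
    double rho = std::sqrt(x * x + y * y);
    double r = p.f_rcyl + (z < p.f_zcc ? (p.f_zcc - z) * p.f_tana : 0.0);
    if (rho > r) {
      double over = rho - r;
      U += 0.5 * p.f_kwall * over * over;
      if (rho > 1e-12) {
        grad[0] += p.f_kwall * over * x / rho;
        grad[1] += p.f_kwall * over * y / rho;
      }
      if (z < p.f_zcc) grad[2] += p.f_kwall * over * p.f_tana;
    }
    if (p.f_zmax > 0 && z > p.f_zmax) {
      double d = z - p.f_zmax;
      U += 0.5 * p.f_kwall * d * d;
      grad[2] += p.f_kwall * d;
    }
  }
  if (p.trap_on) {
    double dx = x - p.cx, dy = y - p.cy, dz = z - p.cz;
    U += 0.5 * p.k_trap * (dx * dx + dy * dy + dz * dz);
    grad[0] += p.k_trap * dx;
    grad[1] += p.k_trap * dy;
    grad[2] += p.k_trap * dz;
  }
  return U;
}

// [[Rcpp::export(name = ".langevin_run")]]
NumericMatrix langevin_run(int n_steps, double dt, int stride,
                           double kT, double gamma,
                           double mass_t, double inertia,
                           NumericVector q0, NumericVector v0,
                           NumericVector bead_rad, NumericVector bead_phase,
                           NumericVector bead_depth,
                           NumericVector bead_center,
                           double well_width,
                           double k_core, double z_core, bool membrane_on,
                           bool funnel_on, double f_alpha, double f_rcyl,
                           double f_zcc, double f_zmax, double f_kwall,
                           bool trap_on, double k_trap,
                           NumericVector trap_center) {
  Params p;
  p.nb = bead_rad.size();
  p.rad = bead_rad.begin();
  p.phase = bead_phase.begin();
  p.depth = bead_depth.begin();
  p.center = bead_center.begin();
  p.w = well_width;
  p.k_core = k_core; p.z_core = z_core;
  p.membrane_on = membrane_on;
  p.funnel_on = funnel_on;
  p.f_tana = std::tan(f_alpha);
  p.f_rcyl = f_rcyl; p.f_zcc = f_zcc; p.f_zmax = f_zmax;
  p.f_kwall = f_kwall;
  p.trap_on = trap_on; p.k_trap = k_trap;
  p.cx = trap_center[0]; p.cy = trap_center[1]; p.cz = trap_center[2];

  double q[4] = { q0[0], q0[1], q0[2], q0[3] };
  double v[4] = { v0[0], v0[1], v0[2], v0[3] };
  double m[4] = { mass_t, mass_t, mass_t, inertia };
  double grad[4];
  double U = potential(p, q[0], q[1], q[2], q[3], grad);

  bool thermo = gamma > 0.0;
  double c1 = thermo ? std::exp(-gamma * dt) : 1.0;
  double c2 = thermo ? std::sqrt(1.0 - c1 * c1) : 0.0;

  int n_samples = n_steps / stride;
  NumericMatrix out(n_samples, 7);
  int row = 0;
  RNGScope rngScope;

  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < 4; ++k) v[k] += -0.5 * dt * grad[k] / m[k]; // B
    for (int k = 0; k < 4; ++k) q[k] += 0.5 * dt * v[k];            // A
    if (thermo) {                                                   // O
      for (int k = 0; k < 4; ++k)
        v[k] = c1 * v[k] + c2 * std::sqrt(kT / m[k]) * norm_rand();
    }
    for (int k = 0; k < 4; ++k) q[k] += 0.5 * dt * v[k];            // A
    U = potential(p, q[0], q[1], q[2], q[3], grad);
    for (int k = 0; k < 4; ++k) v[k] += -0.5 * dt * grad[k] / m[k]; // B
    if (!std::isfinite(q[0]) || !std::isfinite(q[1]) ||
        !std::isfinite(q[2]) || !std::isfinite(q[3]))
      stop("unstable integration: coordinate overflow at step %d "
           "(reduce the time step)", step);
    if (step % stride == 0 && row < n_samples) {
      double kin = 0.0;
      for (int k = 0; k < 4; ++k) kin += 0.5 * m[k] * v[k] * v[k];
      out(row, 0) = step;
      out(row, 1) = q[0]; out(row, 2) = q[1];
      out(row, 3) = q[2]; out(row, 4) = q[3];
      out(row, 5) = U;    out(row, 6) = kin;
      ++row;
    }
  }
  colnames(out) = CharacterVector::create("step", "x", "y", "z", "phi",
                                          "potential", "kinetic");
  return out;
}
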