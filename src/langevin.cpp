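#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin stepper on z in [z_lo, z_hi] with a tabulated reduced
// force f(z) = -dW/dz + qE/V_T (units 1/nm, W in kBT), diffusivity D
// (nm^2/ns) and time step dt (ns):
//   z <- z + D f(z) dt + sqrt(2 D dt) eta
// boundary = 0: absorbing at both ends with immediate re-injection at z_inj
// (single-ion channel, one carrier at a time); signed events recorded
// (+1 at z_hi, -1 at z_lo).  boundary = 1: reflecting at both ends.
// Uses R's RNG so set.seed() governs the trajectory.
// [[Rcpp::export]]
List langevin_run(int n_steps, double dt, double D,
                  NumericVector force_grid, double z_lo, double z_hi,
                  double z_inj, int boundary, int stride) {
  RNGScope scope;
  int ng = force_grid.size();
  double h = (z_hi - z_lo) / (ng - 1);
  double sig = std::sqrt(2.0 * D * dt);
  double z = z_inj;
  int n_rec = n_steps / stride + 1;
  NumericVector zs(n_rec);
  NumericVector ts(n_rec);
  std::vector<double> ev_entry, ev_exit;
  std::vector<int> ev_dir;
  double t_entry = 0.0;
  int irec = 0;
  zs[irec] = z; ts[irec] = 0.0; irec++;
  for (int s = 1; s <= n_steps; ++s) {
    // linear interpolation of the force table
    double u = (z - z_lo) / h;
    int i = (int)std::floor(u);
    if (i < 0) i = 0;
    if (i > ng - 2) i = ng - 2;
    double w = u - i;
    double f = force_grid[i] * (1.0 - w) + force_grid[i + 1] * w;
    z += D * f * dt + sig * norm_rand();
    double t = s * dt;
    if (boundary == 0) {
      if (z >= z_hi) {
        ev_entry.push_back(t_entry); ev_exit.push_back(t); ev_dir.push_back(1);
        z = z_inj; t_entry = t;
      } else if (z <= z_lo) {
        ev_entry.push_back(t_entry); ev_exit.push_back(t); ev_dir.push_back(-1);
        z = z_inj; t_entry = t;
      }
    } else {
      if (z > z_hi) z = 2.0 * z_hi - z;
      if (z < z_lo) z = 2.0 * z_lo - z;
      // a huge diffusive excursion could overshoot twice; clamp
      if (z > z_hi) z = z_hi;
      if (z < z_lo) z = z_lo;
    }
    if (s % stride == 0 && irec < n_rec) {
      zs[irec] = z; ts[irec] = t; irec++;
    }
  }
  return List::create(
    _["times"] = ts, _["positions"] = zs,
    _["entry"] = wrap(ev_entry), _["exit"] = wrap(ev_exit),
    _["direction"] = wrap(ev_dir));
}
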