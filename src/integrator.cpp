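#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Langevin (BAOAB) sampler for the built-in analytic potential families.
// Units: Angstrom, ps, kcal/mol, amu; 1 kcal/mol = 418.4 amu A^2/ps^2.
// The boosted path adds the harmonic boost dV = k/2 (E - V)^2 for V < E,
// which rescales the physical force by (1 - k (E - V)).

static const double KCAL = 418.4;
static const double KB = 0.0019872041;

// kind 1: quartic double well, p = [h, a]
// kind 2: 2D multi-well,      p = [nw, width, wall_h, wall_r0,
//                                  d_1..d_nw, cx_1..cx_nw, cy_1..cy_nw]
static double pot_eval(int kind, const NumericVector& p, const double* x,
                       double* grad) {
  if (kind == 1) {
    double h = p[0], a = p[1];
    double s = (x[0] / a) * (x[0] / a) - 1.0;
    grad[0] = 4.0 * h * x[0] * s / (a * a);
    return h * s * s;
  }
  int nw = (int)p[0];
  double w = p[1], wall_h = p[2], r0 = p[3];
  double r2 = x[0] * x[0] + x[1] * x[1];
  double r04 = r0 * r0 * r0 * r0;
  double v = wall_h * r2 * r2 / r04;
  grad[0] = 4.0 * wall_h * r2 * x[0] / r04;
  grad[1] = 4.0 * wall_h * r2 * x[1] / r04;
  for (int i = 0; i < nw; ++i) {
    double d = p[4 + i], cx = p[4 + nw + i], cy = p[4 + 2 * nw + i];
    double dx = x[0] - cx, dy = x[1] - cy;
    double e = std::exp(-(dx * dx + dy * dy) / (2.0 * w * w));
    v -= d * e;
    grad[0] += d * e * dx / (w * w);
    grad[1] += d * e * dy / (w * w);
  }
  return v;
}

// [[Rcpp::export(name = ".langevin_core_cpp")]]
List langevin_core_cpp(int kind, NumericVector params, NumericVector x0,
                       double mass, double temperature, double friction,
                       double dt, int n_steps, int stride,
                       double boost_E, double boost_k, bool boosted) {
  const int dim = x0.size();
  const double kt = KB * temperature;
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(kt * KCAL / mass * (1.0 - c1 * c1));
  const double vsd = std::sqrt(kt * KCAL / mass);

  double x[2], v[2], g[2], F[2];
  for (int d = 0; d < dim; ++d) x[d] = x0[d];
  for (int d = 0; d < dim; ++d) v[d] = vsd * R::norm_rand();

  double V = pot_eval(kind, params, x, g);
  double dV = 0.0;
  double scale = 1.0;
  if (boosted && V < boost_E) {
    dV = 0.5 * boost_k * (boost_E - V) * (boost_E - V);
    scale = 1.0 - boost_k * (boost_E - V);
  }
  for (int d = 0; d < dim; ++d) F[d] = -g[d] * scale;

  const int n_store = n_steps / stride;
  NumericMatrix coords(n_store, dim);
  NumericVector vser(n_store), dvser(n_store);
  int stored = 0, diverged = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int d = 0; d < dim; ++d) {
      v[d] += 0.5 * dt * F[d] * KCAL / mass;
      x[d] += 0.5 * dt * v[d];
    }
    for (int d = 0; d < dim; ++d)
      v[d] = c1 * v[d] + c2 * R::norm_rand();
    for (int d = 0; d < dim; ++d) x[d] += 0.5 * dt * v[d];

    V = pot_eval(kind, params, x, g);
    dV = 0.0; scale = 1.0;
    if (boosted && V < boost_E) {
      dV = 0.5 * boost_k * (boost_E - V) * (boost_E - V);
      scale = 1.0 - boost_k * (boost_E - V);
    }
    for (int d = 0; d < dim; ++d) {
      F[d] = -g[d] * scale;
      v[d] += 0.5 * dt * F[d] * KCAL / mass;
    }

    if (!std::isfinite(V) || std::fabs(V) > 1e8) { diverged = step; break; }
    if (step % stride == 0 && stored < n_store) {
      for (int d = 0; d < dim; ++d) coords(stored, d) = x[d];
      vser[stored] = V;
      dvser[stored] = dV;
      ++stored;
    }
  }
  return List::create(_["coords"] = coords, _["v"] = vser, _["dv"] = dvser,
                      _["stored"] = stored, _["diverged"] = diverged);
}
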