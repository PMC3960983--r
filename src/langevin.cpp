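#include <Rcpp.h>
using namespace Rcpp;

// Compiled toy-potential kernels. id 1: 1D double well, par = (h, w),
// V = h((x/w)^2-1)^2. id 2: 2D inverted-Gaussian wells + confining
// quartic, par = (k, confine, cx, cy, L, then k rows of
// (centerx, centery, depth, width)).
static double kernel_energy(int id, const double *par, const double *x,
                            int dim) {
  if (id == 1) {
    double u = x[0] / par[1];
    double q = u * u - 1.0;
    return par[0] * q * q;
  }
  int k = (int) par[0];
  double confine = par[1], cx = par[2], cy = par[3], L = par[4];
  double e = 0.0;
  for (int i = 0; i < k; ++i) {
    const double *row = par + 5 + 4 * i;
    double dx = x[0] - row[0], dy = x[1] - row[1];
    double s2 = row[3] * row[3];
    e -= row[2] * std::exp(-(dx * dx + dy * dy) / (2.0 * s2));
  }
  double rx = x[0] - cx, ry = x[1] - cy;
  double r2 = (rx * rx + ry * ry) / (L * L);
  return e + confine * r2 * r2;
}

static void kernel_grad(int id, const double *par, const double *x,
                        int dim, double *g) {
  if (id == 1) {
    double h = par[0], w = par[1];
    double u2 = (x[0] / w) * (x[0] / w);
    g[0] = 4.0 * h * x[0] * (u2 - 1.0) / (w * w);
    return;
  }
  int k = (int) par[0];
  double confine = par[1], cx = par[2], cy = par[3], L = par[4];
  g[0] = 0.0; g[1] = 0.0;
  for (int i = 0; i < k; ++i) {
    const double *row = par + 5 + 4 * i;
    double dx = x[0] - row[0], dy = x[1] - row[1];
    double s2 = row[3] * row[3];
    double a = row[2] * std::exp(-(dx * dx + dy * dy) / (2.0 * s2)) / s2;
    g[0] += a * dx;
    g[1] += a * dy;
  }
  double rx = x[0] - cx, ry = x[1] - cy;
  double r2 = rx * rx + ry * ry;
  double c = confine * 4.0 * r2 / (L * L * L * L);
  g[0] += c * rx;
  g[1] += c * ry;
}

static inline double boost_dv(double v, double E, double alpha) {
  double gap = E - v;
  return gap > 0.0 ? gap * gap / (alpha + gap) : 0.0;
}

static inline double boost_scale(double v, double E, double alpha) {
  double gap = E - v;
  if (gap <= 0.0) return 1.0;
  double r = alpha / (alpha + gap);
  return r * r;
}

// BAOAB Langevin splitting, unit mass. Forces on the boosted surface are
// the unbiased forces scaled by dV*/dV evaluated at the current total
// potential energy. Uses R's RNG (one normal per dof per step) so that
// set.seed() makes runs bit-reproducible and the pure-R integrator can
// replay the identical stream.
// [[Rcpp::export]]
List cpp_langevin(int kernel_id, NumericVector par, NumericVector x0,
                  double dt, double gamma, double kT, int n_steps,
                  int stride, bool use_boost, double boost_E,
                  double boost_alpha) {
  int dim = x0.size();
  int n_save = n_steps / stride;
  NumericVector times(n_save), vout(n_save), dvout(n_save);
  NumericMatrix coords(n_save, dim);
  std::vector<double> x(x0.begin(), x0.end()), v(dim, 0.0), f(dim), g(dim);
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(kT * (1.0 - c1 * c1));

  double vp = kernel_energy(kernel_id, par.begin(), x.data(), dim);
  kernel_grad(kernel_id, par.begin(), x.data(), dim, g.data());
  double s = use_boost ? boost_scale(vp, boost_E, boost_alpha) : 1.0;
  for (int d = 0; d < dim; ++d) f[d] = -s * g[d];

  int err_step = 0;
  int isave = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int d = 0; d < dim; ++d) v[d] += 0.5 * dt * f[d];
    for (int d = 0; d < dim; ++d) x[d] += 0.5 * dt * v[d];
    for (int d = 0; d < dim; ++d) v[d] = c1 * v[d] + c2 * norm_rand();
    for (int d = 0; d < dim; ++d) x[d] += 0.5 * dt * v[d];
    vp = kernel_energy(kernel_id, par.begin(), x.data(), dim);
    if (!R_finite(vp) || std::abs(x[0]) > 1e8) { err_step = step; break; }
    kernel_grad(kernel_id, par.begin(), x.data(), dim, g.data());
    s = use_boost ? boost_scale(vp, boost_E, boost_alpha) : 1.0;
    for (int d = 0; d < dim; ++d) {
      f[d] = -s * g[d];
      v[d] += 0.5 * dt * f[d];
    }
    if (step % stride == 0) {
      times[isave] = step * dt;
      for (int d = 0; d < dim; ++d) coords(isave, d) = x[d];
      vout[isave] = vp;
      dvout[isave] = use_boost ? boost_dv(vp, boost_E, boost_alpha) : 0.0;
      ++isave;
    }
  }
  return List::create(_["times"] = times, _["coords"] = coords,
                      _["v"] = vout, _["dv"] = dvout,
                      _["err_step"] = err_step);
}
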