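#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Euler-Maruyama Langevin integrators on analytic potentials,
// plus a grid-based well-tempered metadynamics driver. Randomness comes from
// R's RNG so set.seed() on the R side makes runs bit-reproducible.
//
// 1D potential codes: 0 flat, 1 harmonic (kappa, x0), 2 symmetric double well
// (barrier h, minima at +/- a): U = h ((x/a)^2 - 1)^2, 3 linear (slope).
// 2D potential codes: 0 flat, 1 separable harmonic (kx, x0, ky, y0),
// 2 double well in x + harmonic in y (h, a, ky).

static inline double force1d(int type, const double *p, double x) {
  switch (type) {
  case 1: return -p[0] * (x - p[1]);
  case 2: {
    double u = x / p[1];
    return -p[0] * 2.0 * (u * u - 1.0) * 2.0 * x / (p[1] * p[1]);
  }
  case 3: return -p[0];
  default: return 0.0;
  }
}

// [[Rcpp::export]]
NumericVector c_langevin_umbrella(int type, NumericVector params,
                                  double center, double spring_k,
                                  int n_steps, double dt, double kT,
                                  double friction, double x0) {
  NumericVector out(n_steps);
  const double *p = params.begin();
  double x = x0;
  double amp = std::sqrt(2.0 * kT * dt / friction);
  for (int i = 0; i < n_steps; ++i) {
    double f = force1d(type, p, x) - spring_k * (x - center);
    x += f * dt / friction + amp * norm_rand();
    out[i] = x;
  }
  return out;
}

static inline void force2d(int type, const double *p, double x, double y,
                           double &fx, double &fy) {
  switch (type) {
  case 1:
    fx = -p[0] * (x - p[1]);
    fy = -p[2] * (y - p[3]);
    break;
  case 2: {
    double u = x / p[1];
    fx = -p[0] * 2.0 * (u * u - 1.0) * 2.0 * x / (p[1] * p[1]);
    fy = -p[2] * y;
    break;
  }
  default: fx = 0.0; fy = 0.0;
  }
}

// Bilinear interpolation on a node-centred grid; clamps to the grid box.
static inline double interp(const std::vector<double> &g, int nx, int ny,
                            double xmin, double dx, double ymin, double dy,
                            double x, double y) {
  double u = (x - xmin) / dx, v = (y - ymin) / dy;
  if (u < 0) u = 0; if (u > nx - 1.000001) u = nx - 1.000001;
  if (v < 0) v = 0; if (v > ny - 1.000001) v = ny - 1.000001;
  int i = static_cast<int>(u), j = static_cast<int>(v);
  double a = u - i, b = v - j;
  const double *col0 = &g[static_cast<size_t>(j) * nx];
  const double *col1 = &g[static_cast<size_t>(j + 1) * nx];
  return (1 - a) * (1 - b) * col0[i] + a * (1 - b) * col0[i + 1] +
         (1 - a) * b * col1[i] + a * b * col1[i + 1];
}

// [[Rcpp::export]]
List c_metadynamics(int type, NumericVector params,
                    int n_steps, double dt, double kT, double friction,
                    double x0, double y0,
                    double hill_h, double hill_w, int stride,
                    double bias_factor,
                    double xmin, double xmax, int nx,
                    double ymin, double ymax, int ny,
                    int record_stride, double wall_k) {
  const double *p = params.begin();
  double dx = (xmax - xmin) / (nx - 1), dy = (ymax - ymin) / (ny - 1);
  std::vector<double> Vg(static_cast<size_t>(nx) * ny, 0.0);
  std::vector<double> Gx(Vg.size(), 0.0), Gy(Vg.size(), 0.0);

  int n_rec = n_steps / record_stride;
  NumericMatrix traj(n_rec, 4);  // step, x, y, bias
  double x = x0, y = y0;
  double amp = std::sqrt(2.0 * kT * dt / friction);
  double w2 = hill_w * hill_w;
  int patch = static_cast<int>(std::ceil(5.0 * hill_w / std::min(dx, dy))) + 1;
  int rec = 0;

  for (int s = 1; s <= n_steps; ++s) {
    double fx, fy;
    force2d(type, p, x, y, fx, fy);
    // bias force from gradient grids
    fx -= interp(Gx, nx, ny, xmin, dx, ymin, dy, x, y);
    fy -= interp(Gy, nx, ny, xmin, dx, ymin, dy, x, y);
    // one-sided harmonic walls keep the walker on the grid
    if (x < xmin) fx -= wall_k * (x - xmin);
    if (x > xmax) fx -= wall_k * (x - xmax);
    if (y < ymin) fy -= wall_k * (y - ymin);
    if (y > ymax) fy -= wall_k * (y - ymax);

    x += fx * dt / friction + amp * norm_rand();
    y += fy * dt / friction + amp * norm_rand();

    if (hill_h > 0.0 && s % stride == 0) {
      double vb = interp(Vg, nx, ny, xmin, dx, ymin, dy, x, y);
      double h = hill_h * std::exp(-vb / ((bias_factor - 1.0) * kT));
      int ic = static_cast<int>(std::floor((x - xmin) / dx));
      int jc = static_cast<int>(std::floor((y - ymin) / dy));
      int ilo = std::max(0, ic - patch), ihi = std::min(nx - 1, ic + patch);
      int jlo = std::max(0, jc - patch), jhi = std::min(ny - 1, jc + patch);
      for (int j = jlo; j <= jhi; ++j) {
        double gy = ymin + j * dy, ddy = gy - y;
        for (int i = ilo; i <= ihi; ++i) {
          double gx = xmin + i * dx, ddx = gx - x;
          double g = h * std::exp(-(ddx * ddx + ddy * ddy) / (2.0 * w2));
          size_t idx = static_cast<size_t>(j) * nx + i;
          Vg[idx] += g;
          Gx[idx] += -ddx / w2 * g;  // d/dgx of the Gaussian
          Gy[idx] += -ddy / w2 * g;
        }
      }
    }

    if (s % record_stride == 0 && rec < n_rec) {
      traj(rec, 0) = s;
      traj(rec, 1) = x;
      traj(rec, 2) = y;
      traj(rec, 3) = interp(Vg, nx, ny, xmin, dx, ymin, dy, x, y);
      ++rec;
    }
  }

  NumericMatrix grid(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      grid(i, j) = Vg[static_cast<size_t>(j) * nx + i];
  return List::create(_["traj"] = traj, _["bias"] = grid);
}
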