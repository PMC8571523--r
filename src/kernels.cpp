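#include <Rcpp.h>
#include <cmath>
#include <array>
#include <vector>
using namespace Rcpp;

// Boltzmann constant in kJ/(mol K)
static const double KB_KJ = 0.0083144621;

// Sample a discrete Markov chain from per-row cumulative transition
// probabilities. Uses R's RNG so set.seed() governs reproducibility.
// States are 1-based on the R side.
// [[Rcpp::export]]
IntegerVector cpp_sample_chain(NumericMatrix cumT, int n_steps, int start) {
  const int n = cumT.nrow();
  IntegerVector out(n_steps);
  int s = start - 1;
  out[0] = s + 1;
  for (int t = 1; t < n_steps; ++t) {
    const double u = unif_rand();
    int k = 0;
    while (k < n - 1 && cumT(s, k) <= u) ++k;
    s = k;
    out[t] = s + 1;
  }
  return out;
}

// First-passage times (in steps) from `start` into the target set, repeated
// n_rep times. NA if max_steps is exceeded (censored).
// [[Rcpp::export]]
NumericVector cpp_first_passage(NumericMatrix cumT, int start,
                                LogicalVector target, int n_rep,
                                double max_steps) {
  const int n = cumT.nrow();
  NumericVector out(n_rep);
  for (int r = 0; r < n_rep; ++r) {
    int s = start - 1;
    double t = 0.0;
    bool hit = false;
    while (t < max_steps) {
      const double u = unif_rand();
      int k = 0;
      while (k < n - 1 && cumT(s, k) <= u) ++k;
      s = k;
      t += 1.0;
      if (target[s]) { hit = true; break; }
    }
    out[r] = hit ? t : NA_REAL;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Toy energy landscapes: a sum of radial basins inside a reflecting box.
// shape 0: Gaussian wells  U = -sum_k D_k exp(-r_k^2 / (2 w_k^2))
// shape 1: harmonic wells  U =  sum_k 0.5 * (D_k / w_k^2) * r_k^2
// Units: nm, kJ/mol.
// ---------------------------------------------------------------------------

static void landscape_grad(const double* x, int d,
                           const NumericMatrix& centers,
                           const NumericVector& depths,
                           const NumericVector& widths,
                           int shape, double* g) {
  for (int j = 0; j < d; ++j) g[j] = 0.0;
  const int nb = centers.nrow();
  for (int k = 0; k < nb; ++k) {
    double r2 = 0.0;
    for (int j = 0; j < d; ++j) {
      const double dx = x[j] - centers(k, j);
      r2 += dx * dx;
    }
    const double w2 = widths[k] * widths[k];
    if (shape == 0) {
      const double pref = depths[k] * std::exp(-r2 / (2.0 * w2)) / w2;
      for (int j = 0; j < d; ++j) g[j] += pref * (x[j] - centers(k, j));
    } else {
      const double kspring = depths[k] / w2;
      for (int j = 0; j < d; ++j) g[j] += kspring * (x[j] - centers(k, j));
    }
  }
}

static inline void reflect(double* x, int d, double L) {
  for (int j = 0; j < d; ++j) {
    while (x[j] > L || x[j] < -L) {
      if (x[j] > L) x[j] = 2.0 * L - x[j];
      if (x[j] < -L) x[j] = -2.0 * L - x[j];
    }
  }
}

// Overdamped Langevin dynamics on a toy landscape with reflecting walls.
// x <- x - (dt/gamma) grad U + sqrt(2 kT dt / gamma) xi
// Positions are recorded every `thin` steps (the initial position included).
// [[Rcpp::export]]
NumericMatrix cpp_langevin(NumericMatrix centers, NumericVector depths,
                           NumericVector widths, int shape, double half_box,
                           double dt, double kT, double gamma, int n_steps,
                           NumericVector x0, int thin) {
  const int d = x0.size();
  const int n_save = n_steps / thin + 1;
  NumericMatrix out(n_save, d);
  std::vector<double> x(d), g(d);
  for (int j = 0; j < d; ++j) { x[j] = x0[j]; out(0, j) = x[j]; }
  const double mob = dt / gamma;
  const double noise = std::sqrt(2.0 * kT * dt / gamma);
  int isave = 1;
  for (int t = 1; t <= n_steps; ++t) {
    landscape_grad(x.data(), d, centers, depths, widths, shape, g.data());
    for (int j = 0; j < d; ++j) x[j] += -mob * g[j] + noise * norm_rand();
    reflect(x.data(), d, half_box);
    if (t % thin == 0) {
      for (int j = 0; j < d; ++j) out(isave, j) = x[j];
      ++isave;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Collective variables for the metadynamics engine.
// type 0: position      s = x[dim]                    (param: dim, 0-based)
// type 1: distance      s = |x - ref|                 (param: ref point)
// type 2: contact count s = sum_i 1/(1 + (r_i/r0)^6)  (param: site coords, r0)
// ---------------------------------------------------------------------------

struct CVDef {
  int type;
  int dim;                 // position CV
  std::vector<double> ref; // distance CV
  NumericMatrix sites;     // contact CV
  double r0;
};

static double cv_value(const CVDef& cv, const double* x, int d) {
  if (cv.type == 0) return x[cv.dim];
  if (cv.type == 1) {
    double r2 = 0.0;
    for (int j = 0; j < d; ++j) {
      const double dx = x[j] - cv.ref[j];
      r2 += dx * dx;
    }
    return std::sqrt(r2);
  }
  double s = 0.0;
  for (int i = 0; i < cv.sites.nrow(); ++i) {
    double r2 = 0.0;
    for (int j = 0; j < d; ++j) {
      const double dx = x[j] - cv.sites(i, j);
      r2 += dx * dx;
    }
    const double u = std::sqrt(r2) / cv.r0;
    s += 1.0 / (1.0 + u * u * u * u * u * u);
  }
  return s;
}

// ds/dx
static void cv_grad(const CVDef& cv, const double* x, int d, double* g) {
  for (int j = 0; j < d; ++j) g[j] = 0.0;
  if (cv.type == 0) { g[cv.dim] = 1.0; return; }
  if (cv.type == 1) {
    double r2 = 0.0;
    for (int j = 0; j < d; ++j) {
      const double dx = x[j] - cv.ref[j];
      r2 += dx * dx;
    }
    const double r = std::sqrt(r2);
    if (r < 1e-12) return; // gradient undefined at the reference point
    for (int j = 0; j < d; ++j) g[j] = (x[j] - cv.ref[j]) / r;
    return;
  }
  for (int i = 0; i < cv.sites.nrow(); ++i) {
    double r2 = 0.0;
    for (int j = 0; j < d; ++j) {
      const double dx = x[j] - cv.sites(i, j);
      r2 += dx * dx;
    }
    const double r = std::sqrt(r2);
    if (r < 1e-12) continue;
    const double u = r / cv.r0;
    const double u6 = u * u * u * u * u * u;
    const double denom = (1.0 + u6) * (1.0 + u6);
    // df/dx = (df/dr) dx/r with df/dr = -6 u^6 / (r (1+u^6)^2)
    const double pref = -6.0 * u6 / (r * r * denom);
    for (int j = 0; j < d; ++j) g[j] += pref * (x[j] - cv.sites(i, j));
  }
}

// Well-tempered metadynamics on a toy landscape. The time-dependent bias
// V(s,t) is a sum of Gaussians deposited every `stride` steps with
// effective height h * exp(-V(s_dep)/(kB dT)), dT = (gamma_b - 1) T.
// The bias and its CV-gradient are accumulated on a fixed grid (tails
// truncated at 6 widths) and interpolated linearly during propagation.
// Supports 1 or 2 CVs.
// [[Rcpp::export]]
List cpp_wtmetad(NumericMatrix centers, NumericVector depths,
                 NumericVector widths, int shape, double half_box,
                 double dt, double kT, double gamma, int n_steps,
                 NumericVector x0, int thin,
                 List cv_list, double hill_h, NumericVector hill_w,
                 int stride, double bias_factor, double temp,
                 NumericVector gmin, NumericVector gmax,
                 IntegerVector gn) {
  const int d = x0.size();
  const int ncv = cv_list.size();
  std::vector<CVDef> cvs(ncv);
  for (int c = 0; c < ncv; ++c) {
    List cvl = cv_list[c];
    CVDef cv;
    cv.type = as<int>(cvl["type"]);
    cv.dim = 0;
    cv.r0 = 0.0;
    if (cv.type == 0) cv.dim = as<int>(cvl["dim"]) - 1;
    if (cv.type == 1) cv.ref = as<std::vector<double> >(cvl["ref"]);
    if (cv.type == 2) {
      cv.sites = as<NumericMatrix>(cvl["sites"]);
      cv.r0 = as<double>(cvl["r0"]);
    }
    cvs[c] = cv;
  }

  const double dT = (bias_factor - 1.0) * temp;
  const double kbdT = KB_KJ * dT;

  // grid storage: flattened (ncv == 1 or 2)
  const int n1 = gn[0];
  const int n2 = (ncv == 2) ? gn[1] : 1;
  const double d1 = (gmax[0] - gmin[0]) / (n1 - 1);
  const double d2 = (ncv == 2) ? (gmax[1] - gmin[1]) / (n2 - 1) : 1.0;
  std::vector<double> V((size_t)n1 * n2, 0.0);
  std::vector<double> G1((size_t)n1 * n2, 0.0);
  std::vector<double> G2(ncv == 2 ? (size_t)n1 * n2 : 1, 0.0);
  // index helper: V[i + n1*j]

  const int n_save = n_steps / thin + 1;
  NumericMatrix pos(n_save, d);
  NumericMatrix cvtraj(n_save, ncv);
  std::vector<std::array<double, 8> > hills;

  std::vector<double> x(d), g(d), cg(d);
  std::vector<double> s(ncv);
  for (int j = 0; j < d; ++j) { x[j] = x0[j]; pos(0, j) = x[j]; }
  for (int c = 0; c < ncv; ++c) cvtraj(0, c) = cv_value(cvs[c], x.data(), d);

  const double mob = dt / gamma;
  const double noise = std::sqrt(2.0 * kT * dt / gamma);

  // bilinear interpolation of V, G1, G2 at cv point
  auto interp = [&](const std::vector<double>& A, double s1v, double s2v) {
    double f1 = (s1v - gmin[0]) / d1;
    int i1 = (int)std::floor(f1);
    if (i1 < 0) { i1 = 0; f1 = 0.0; }
    if (i1 >= n1 - 1) { i1 = n1 - 2; f1 = (double)(n1 - 1); }
    const double t1 = f1 - i1;
    if (ncv == 1) return (1.0 - t1) * A[i1] + t1 * A[i1 + 1];
    double f2 = (s2v - gmin[1]) / d2;
    int i2 = (int)std::floor(f2);
    if (i2 < 0) { i2 = 0; f2 = 0.0; }
    if (i2 >= n2 - 1) { i2 = n2 - 2; f2 = (double)(n2 - 1); }
    const double t2 = f2 - i2;
    const double v00 = A[i1 + (size_t)n1 * i2];
    const double v10 = A[i1 + 1 + (size_t)n1 * i2];
    const double v01 = A[i1 + (size_t)n1 * (i2 + 1)];
    const double v11 = A[i1 + 1 + (size_t)n1 * (i2 + 1)];
    return (1.0 - t1) * (1.0 - t2) * v00 + t1 * (1.0 - t2) * v10 +
           (1.0 - t1) * t2 * v01 + t1 * t2 * v11;
  };

  int isave = 1;
  for (int t = 1; t <= n_steps; ++t) {
    // deposit a hill?
    if (stride >= 1 && t % stride == 0) {
      for (int c = 0; c < ncv; ++c) s[c] = cv_value(cvs[c], x.data(), d);
      const double vhere = interp(V, s[0], ncv == 2 ? s[1] : 0.0);
      const double heff = hill_h * std::exp(-vhere / kbdT);
      // accumulate Gaussian on the grid, truncated at 6 sigma
      const int lo1 = std::max(0, (int)std::floor((s[0] - 6.0 * hill_w[0] - gmin[0]) / d1));
      const int hi1 = std::min(n1 - 1, (int)std::ceil((s[0] + 6.0 * hill_w[0] - gmin[0]) / d1));
      const int lo2 = (ncv == 2)
          ? std::max(0, (int)std::floor((s[1] - 6.0 * hill_w[1] - gmin[1]) / d2)) : 0;
      const int hi2 = (ncv == 2)
          ? std::min(n2 - 1, (int)std::ceil((s[1] + 6.0 * hill_w[1] - gmin[1]) / d2)) : 0;
      for (int i2 = lo2; i2 <= hi2; ++i2) {
        double e2 = 1.0, dz2 = 0.0;
        if (ncv == 2) {
          dz2 = gmin[1] + i2 * d2 - s[1];
          e2 = std::exp(-dz2 * dz2 / (2.0 * hill_w[1] * hill_w[1]));
        }
        for (int i1 = lo1; i1 <= hi1; ++i1) {
          const double dz1 = gmin[0] + i1 * d1 - s[0];
          const double e1 = std::exp(-dz1 * dz1 / (2.0 * hill_w[0] * hill_w[0]));
          const double val = heff * e1 * e2;
          const size_t idx = i1 + (size_t)n1 * i2;
          V[idx] += val;
          G1[idx] += val * (-dz1 / (hill_w[0] * hill_w[0]));
          if (ncv == 2) G2[idx] += val * (-dz2 / (hill_w[1] * hill_w[1]));
        }
      }
      std::array<double, 8> h = {t * dt, s[0], ncv == 2 ? s[1] : NA_REAL,
                                 hill_w[0], ncv == 2 ? hill_w[1] : NA_REAL,
                                 heff, bias_factor, vhere};
      hills.push_back(h);
    }
    // forces: physical + bias (chain rule through the CVs)
    landscape_grad(x.data(), d, centers, depths, widths, shape, g.data());
    for (int c = 0; c < ncv; ++c) s[c] = cv_value(cvs[c], x.data(), d);
    const double dVds1 = interp(G1, s[0], ncv == 2 ? s[1] : 0.0);
    const double dVds2 = (ncv == 2) ? interp(G2, s[0], s[1]) : 0.0;
    cv_grad(cvs[0], x.data(), d, cg.data());
    for (int j = 0; j < d; ++j) g[j] += dVds1 * cg[j];
    if (ncv == 2) {
      cv_grad(cvs[1], x.data(), d, cg.data());
      for (int j = 0; j < d; ++j) g[j] += dVds2 * cg[j];
    }
    for (int j = 0; j < d; ++j) x[j] += -mob * g[j] + noise * norm_rand();
    reflect(x.data(), d, half_box);
    if (t % thin == 0) {
      for (int j = 0; j < d; ++j) pos(isave, j) = x[j];
      for (int c = 0; c < ncv; ++c) cvtraj(isave, c) = cv_value(cvs[c], x.data(), d);
      ++isave;
    }
  }

  NumericMatrix hm(hills.size(), 8);
  for (size_t i = 0; i < hills.size(); ++i)
    for (int j = 0; j < 8; ++j) hm(i, j) = hills[i][j];
  colnames(hm) = CharacterVector::create("time", "center1", "center2",
                                         "width1", "width2", "height",
                                         "bias_factor", "bias_at_center");

  NumericVector vgrid(V.begin(), V.end());
  return List::create(_["positions"] = pos, _["cv"] = cvtraj,
                      _["hills"] = hm, _["bias_grid"] = vgrid);
}
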