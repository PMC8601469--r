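#include <Rcpp.h>
using namespace Rcpp;

// Site type codes shared with the R side: 0 = EMPTY, 1 = PROACTIVE, 2 = REACTIVE.
// Boundary codes: 0 = no-flux (out-of-grid neighbor takes the edge value),
// 1 = periodic (wraparound).

static inline int reflect(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}
static inline int wrap(int i, int n) {
  if (i < 0) return i + n;
  if (i >= n) return i - n;
  return i;
}

// 5-point Laplacian of `f` at (i, j) under boundary convention `bc`.
static inline double lap5(const double* f, int nr, int nc, int i, int j,
                          int bc, double inv_h2) {
  int iu, id, jl, jr;
  if (bc == 1) {
    iu = wrap(i - 1, nr); id = wrap(i + 1, nr);
    jl = wrap(j - 1, nc); jr = wrap(j + 1, nc);
  } else {
    iu = reflect(i - 1, nr); id = reflect(i + 1, nr);
    jl = reflect(j - 1, nc); jr = reflect(j + 1, nc);
  }
  double c = f[i + (R_xlen_t)j * nr];
  return (f[iu + (R_xlen_t)j * nr] + f[id + (R_xlen_t)j * nr] +
          f[i + (R_xlen_t)jl * nr] + f[i + (R_xlen_t)jr * nr] - 4.0 * c) * inv_h2;
}

// [[Rcpp::export]]
NumericMatrix laplacian_cpp(NumericMatrix field, int bc, double h) {
  int nr = field.nrow(), nc = field.ncol();
  NumericMatrix out(nr, nc);
  double inv_h2 = 1.0 / (h * h);
  const double* f = field.begin();
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = lap5(f, nr, nc, i, j, bc, inv_h2);
  return out;
}

// Mean over all sites of the 1/4-weighted centered product with the four
// von Neumann neighbors; edge lookups follow the simulator's bc convention.
// [[Rcpp::export]]
double neighbor_cov_cpp(NumericMatrix u, int bc) {
  int nr = u.nrow(), nc = u.ncol();
  R_xlen_t n = (R_xlen_t)nr * nc;
  const double* f = u.begin();
  double ubar = 0.0;
  for (R_xlen_t k = 0; k < n; ++k) ubar += f[k];
  ubar /= (double)n;
  double acc = 0.0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int iu, id, jl, jr;
      if (bc == 1) {
        iu = wrap(i - 1, nr); id = wrap(i + 1, nr);
        jl = wrap(j - 1, nc); jr = wrap(j + 1, nc);
      } else {
        iu = reflect(i - 1, nr); id = reflect(i + 1, nr);
        jl = reflect(j - 1, nc); jr = reflect(j + 1, nc);
      }
      double du = f[i + (R_xlen_t)j * nr] - ubar;
      double s = (f[iu + (R_xlen_t)j * nr] - ubar) + (f[id + (R_xlen_t)j * nr] - ubar) +
                 (f[i + (R_xlen_t)jl * nr] - ubar) + (f[i + (R_xlen_t)jr * nr] - ubar);
      acc += du * s * 0.25;
    }
  }
  return acc / (double)n;
}

struct StepPars {
  double a, b, eps, delta, D, lam, dt, h, Du, decay, u_cap;
  int bc;
  bool shared_noise;
  // precomputed OU factors
  double rho, sd1;
};

static StepPars unpack(const List& par) {
  StepPars p;
  p.a = as<double>(par["a"]);
  p.b = as<double>(par["b"]);
  p.eps = as<double>(par["epsilon"]);
  p.delta = as<double>(par["delta"]);
  p.D = as<double>(par["D"]);
  p.lam = as<double>(par["lam"]);
  p.dt = as<double>(par["dt"]);
  p.h = as<double>(par["h"]);
  p.Du = as<double>(par["D_u"]);
  p.decay = as<double>(par["decay"]);
  double uc = as<double>(par["u_cap"]);
  p.u_cap = R_finite(uc) ? uc : R_PosInf;
  p.bc = as<int>(par["bc_code"]);
  p.shared_noise = as<bool>(par["shared_noise"]);
  p.rho = std::exp(-p.lam * p.dt);
  p.sd1 = std::sqrt(p.D * (1.0 - p.rho * p.rho));
  return p;
}

// Advance the full field state by n_iter time steps, recording the spatial
// mean, spatial standard deviation and von Neumann neighbor covariance of u
// after every step, one lattice row of u after every step, and full u/v
// snapshots at a stride.  RNG: R's own generator (draws are made in
// column-major site order, one per occupied site per step, so runs are
// reproducible under set.seed()).
//
// The neighbor covariance is folded into the stencil sweep via the identity
//   Cov = (h^2 * sum(u * lap(u)) + 4 * sum(u^2)) / (4 N^2) - ubar^2,
// which holds for both boundary conventions because the (mirrored/wrapped)
// neighbor relation is symmetric; the step that consumes field t therefore
// also emits the statistics of field t, and one trailing sweep covers the
// final field.
// [[Rcpp::export]]
List advance_cpp(IntegerMatrix type, NumericMatrix u_in, NumericMatrix v_in,
                 NumericMatrix eta_in, List par, int n_iter, int record_every,
                 bool record_fields, int kymo_row, int iter0) {
  const int nr = type.nrow(), nc = type.ncol();
  const R_xlen_t n = (R_xlen_t)nr * nc;
  StepPars p = unpack(par);
  const double inv_h2 = 1.0 / (p.h * p.h);
  const double h2 = p.h * p.h;

  NumericMatrix u(clone(u_in)), v(clone(v_in)), eta(clone(eta_in));
  NumericMatrix unew(nr, nc);

  NumericVector ubar_s(n_iter), sigma_s(n_iter), cov_s(n_iter);
  IntegerVector iters(n_iter);
  NumericMatrix midrow(n_iter, nc);

  std::vector<NumericMatrix> snaps_u, snaps_v;
  std::vector<int> snap_iters;

  const int* tp = type.begin();

  // emit statistics of the field recorded after step `it` (1-based)
  auto record_stats = [&](int it, double s1, double s2, double cross) {
    double ub = s1 / (double)n;
    double var = s2 / (double)n - ub * ub;
    if (var < 0.0) var = 0.0;
    if (!R_finite(ub) || !R_finite(var)) {
      const double* uf = u.begin();
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i)
          if (!R_finite(uf[i + (R_xlen_t)j * nr]))
            stop("non-finite u at iteration %d, site (%d, %d): reduce dt",
                 iter0 + it, i + 1, j + 1);
      stop("non-finite field statistics at iteration %d: reduce dt",
           iter0 + it);
    }
    int idx = it - 1;
    iters[idx] = iter0 + it;
    ubar_s[idx] = ub;
    sigma_s[idx] = std::sqrt(var);
    cov_s[idx] = (h2 * cross + 4.0 * s2) / (4.0 * (double)n) - ub * ub;
  };

  for (int it = 1; it <= n_iter + 1; ++it) {
    const double* uf = u.begin();
    double* vf = v.begin();
    double* ef = eta.begin();
    double* un = unew.begin();
    const bool stepping = it <= n_iter;

    double shared_z = (stepping && p.shared_noise) ? norm_rand() : 0.0;
    double s1 = 0.0, s2 = 0.0, cross = 0.0;

    for (int j = 0; j < nc; ++j) {
      const R_xlen_t col = (R_xlen_t)j * nr;
      const int jl = (p.bc == 1) ? wrap(j - 1, nc) : reflect(j - 1, nc);
      const int jr = (p.bc == 1) ? wrap(j + 1, nc) : reflect(j + 1, nc);
      const double* cC = uf + col;
      const double* cL = uf + (R_xlen_t)jl * nr;
      const double* cR = uf + (R_xlen_t)jr * nr;

      for (int i = 0; i < nr; ++i) {
        const int iu = (i == 0) ? ((p.bc == 1) ? nr - 1 : 0) : i - 1;
        const int id = (i == nr - 1) ? ((p.bc == 1) ? 0 : nr - 1) : i + 1;
        const double uc = cC[i];
        const double lap = (cC[iu] + cC[id] + cL[i] + cR[i] - 4.0 * uc) * inv_h2;

        s1 += uc; s2 += uc * uc; cross += uc * lap;

        if (!stepping) continue;
        if (std::abs(uc) > p.u_cap)
          stop("|u| exceeded u_cap (%g) at iteration %d, site (%d, %d): "
               "numerical blow-up suspected", p.u_cap, iter0 + it, i + 1, j + 1);

        const R_xlen_t k = col + i;
        const int ty = tp[k];
        const double diff = p.dt * p.Du * lap;

        if (ty == 0) {                       // empty: diffusion (+ optional decay)
          un[k] = uc + diff - p.dt * p.decay * uc;
          continue;
        }

        const double vc = vf[k];
        const double uth = (vc + p.b) / p.a;

        if (uc < p.delta && uc <= uth) {
          // boundary layer: sub-delta, sub-threshold u decays to the rest
          // fixed point, so the reaction is skipped (fast-slow treatment; v
          // keeps relaxing below).  A cell whose noise-lowered threshold
          // falls under its current u is excited and does react: this is
          // the noise-nucleation (pacemaker) pathway.
          un[k] = uc + diff;
        } else if (ty == 1) {                // proactive: Barkley cubic kinetics
          // semi-implicit logistic update with the (u - u_th) factor frozen
          double g = (uc - uth) / p.eps;
          double ur;
          if (g <= 0.0)
            ur = uc / (1.0 - p.dt * g * (1.0 - uc));
          else
            ur = 1.0 - (1.0 - uc) / (1.0 + p.dt * g * uc);
          un[k] = ur + diff;
        } else {                             // reactive: linear kinetics, no eps
          double ur = uc + p.dt * (uc - uth) + diff;
          // u is a concentration: the linear response saturates at zero
          un[k] = (ur < 0.0) ? 0.0 : ur;
        }

        // recovery variable, then its OU noise (both from pre-step values)
        vf[k] = vc + p.dt * (uc - vc + ef[k]);
        double z = p.shared_noise ? shared_z : norm_rand();
        ef[k] = ef[k] * p.rho + p.sd1 * z;
      }
    }

    // the sweep above consumed the field written by step it-1
    if (it > 1) record_stats(it - 1, s1, s2, cross);
    if (!stepping) break;

    std::swap(u, unew);

    // cheap per-step records of the fresh field
    const double* ufn = u.begin();
    int idx = it - 1;
    for (int j = 0; j < nc; ++j) midrow(idx, j) = ufn[kymo_row + (R_xlen_t)j * nr];
    if (record_fields && (it % record_every == 0 || it == n_iter)) {
      snaps_u.push_back(clone(u));
      snaps_v.push_back(clone(v));
      snap_iters.push_back(iter0 + it);
    }
  }

  List su(snaps_u.size()), sv(snaps_v.size());
  for (size_t s = 0; s < snaps_u.size(); ++s) { su[s] = snaps_u[s]; sv[s] = snaps_v[s]; }

  return List::create(
    _["u"] = u, _["v"] = v, _["eta"] = eta,
    _["iterations"] = iters, _["ubar"] = ubar_s, _["sigma"] = sigma_s,
    _["cov"] = cov_s, _["midrow"] = midrow,
    _["snap_iterations"] = wrap(snap_iters),
    _["snapshots_u"] = su, _["snapshots_v"] = sv);
}
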