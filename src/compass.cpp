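// Compiled inner loop of the stability-constrained gLV inverse problem:
// the penalized objective (spectral-abscissa hinge + L1 sparsity +
// RK4 trajectory misfit in composition space) and the compass direct
// search over the entries of the interaction matrix. Mirrors the pure-R
// reference implementation (glv_objective / direct_search).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double kOverflow = 1e6;
const double kDt = 0.5;

struct Observation {
  std::vector<double> times;
  std::vector<std::vector<double>> states;   // states[k] = composition at k
  std::vector<std::vector<double>> clr;      // centered log-ratio of states
  std::vector<std::vector<double>> weights;  // inverse-variance weights
};

struct Workspace {
  int n;
  std::vector<double> y, r, k1, k2, k3, k4, tmp;
  arma::mat J;
  Workspace(int n_)
      : n(n_), y(n_), r(n_), k1(n_), k2(n_), k3(n_), k4(n_), tmp(n_),
        J(n_, n_) {}
};

// dy = diag(y)(r + A y); A column-major n x n
inline void rhs(const double* A, const double* r, const double* y, int n,
                double* dy) {
  for (int i = 0; i < n; ++i) dy[i] = r[i];
  for (int j = 0; j < n; ++j) {
    const double yj = y[j];
    const double* col = A + (size_t)j * n;
    for (int i = 0; i < n; ++i) dy[i] += col[i] * yj;
  }
  for (int i = 0; i < n; ++i) dy[i] *= y[i];
}

// fixed-step RK4 misfit of predicted against observed compositions in
// centered-log-ratio space (respects the multiplicative noise model and
// cancels the common-mode error of per-sample renormalization). The
// trajectory's first state is the initial condition and the forecast runs
// through its full horizon. Returns false on divergence.
bool rk4_sse(const double* A, const double* r, const Observation& ob,
             Workspace& w, double& sse, const double* y0 = nullptr) {
  const int n = w.n;
  double* y = w.y.data();
  for (int i = 0; i < n; ++i) y[i] = y0 ? y0[i] : ob.states[0][i];
  sse = 0.0;
  for (size_t k = 1; k < ob.times.size(); ++k) {
    double t0 = ob.times[k - 1], t1 = ob.times[k];
    int nstep = std::max(1, (int)std::ceil((t1 - t0) / kDt));
    double h = (t1 - t0) / nstep;
    for (int s = 0; s < nstep; ++s) {
      rhs(A, r, y, n, w.k1.data());
      for (int i = 0; i < n; ++i) w.tmp[i] = y[i] + (h / 2) * w.k1[i];
      rhs(A, r, w.tmp.data(), n, w.k2.data());
      for (int i = 0; i < n; ++i) w.tmp[i] = y[i] + (h / 2) * w.k2[i];
      rhs(A, r, w.tmp.data(), n, w.k3.data());
      for (int i = 0; i < n; ++i) w.tmp[i] = y[i] + h * w.k3[i];
      rhs(A, r, w.tmp.data(), n, w.k4.data());
      double amax = 0.0;
      bool ok = true;
      for (int i = 0; i < n; ++i) {
        y[i] += (h / 6) * (w.k1[i] + 2 * w.k2[i] + 2 * w.k3[i] + w.k4[i]);
        if (!std::isfinite(y[i])) ok = false;
        amax = std::max(amax, std::fabs(y[i]));
      }
      if (!ok || amax > kOverflow) return false;
    }
    double lmean = 0.0;
    for (int i = 0; i < n; ++i) {
      if (y[i] <= 1e-12) return false;
      w.tmp[i] = std::log(y[i]);
      lmean += w.tmp[i];
    }
    lmean /= n;
    for (int i = 0; i < n; ++i) {
      double d = (w.tmp[i] - lmean) - ob.clr[k][i];
      sse += ob.weights[k][i] * d * d;
    }
  }
  return true;
}

// Aext is n x n (plain interaction matrix), (n+1) x n (row n: log-scale
// equilibrium refinement u, penalized by its standard errors se_rel), or
// (n+1+S) x n with one extra row of log-scale latent-initial-state
// deviations per fitted trajectory, penalized by the start's
// log-observation weights.
double objective(const arma::mat& Aext, const arma::vec& ybar_est,
                 const arma::vec& se_rel,
                 const std::vector<Observation>& obs, double fit_weight,
                 double margin, double sparsity_weight, int nobs_total,
                 Workspace& w) {
  const int n = w.n;
  const int S = (int)obs.size();
  const bool refine = (int)Aext.n_rows > n;
  const bool latent = (int)Aext.n_rows == n + 1 + S && S > 0;
  const arma::mat A = Aext.head_rows(n);
  arma::vec ybar = ybar_est;
  double eq_pen = 0.0;
  if (refine) {
    for (int i = 0; i < n; ++i) {
      double u = Aext(n, i);
      ybar[i] = ybar_est[i] * std::exp(u);
      double z = u / se_rel[i];
      eq_pen += z * z;
    }
  }
  // r = -A ybar, and J = diag(r + A ybar) + diag(ybar) A = diag(ybar) A
  // exactly (the diagonal term cancels by construction of r)
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += A(i, j) * ybar[j];
    w.r[i] = -s;
  }
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) w.J(i, j) = ybar[i] * A(i, j);
  arma::cx_vec ev;
  if (!arma::eig_gen(ev, w.J)) return R_PosInf;
  double sa = arma::real(ev).max();
  double hinge = std::max(0.0, sa + margin);
  double obj = hinge * hinge;
  double l1 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) l1 += std::fabs(A(i, j));
  obj += sparsity_weight * l1;
  if (!obs.empty() && fit_weight > 0) {
    double sse_total = eq_pen;
    int denom = nobs_total + (refine ? n : 0);
    std::vector<double> y0(n);
    for (int sidx = 0; sidx < S; ++sidx) {
      const Observation& ob = obs[sidx];
      double sse;
      const double* y0p = nullptr;
      if (latent) {
        for (int i = 0; i < n; ++i) {
          double vi = Aext(n + 1 + sidx, i);
          y0[i] = ob.states[0][i] * std::exp(vi);
          sse_total += vi * vi * ob.weights[0][i];
        }
        denom += n;
        y0p = y0.data();
      }
      if (!rk4_sse(A.memptr(), w.r.data(), ob, w, sse, y0p))
        return R_PosInf;
      sse_total += sse;
    }
    obj += fit_weight * sse_total / denom;
  }
  return obj;
}

}  // namespace

// [[Rcpp::export]]
List compass_search_glv(const arma::mat& A0, const arma::vec& y_bar,
                        const arma::vec& y_bar_se_rel,
                        List observations, double fit_weight, double margin,
                        double sparsity_weight, bool diag_constraint,
                        double step_init, double step_contract,
                        double step_tol, int max_iters) {
  const int n = y_bar.n_elem;

  Workspace w(n);
  std::vector<Observation> obs;
  int nobs_total = 0;
  for (R_xlen_t k = 0; k < observations.size(); ++k) {
    List ob = observations[k];
    NumericVector times = ob["times"];
    NumericMatrix states = ob["states"];
    NumericMatrix clr = ob["clr"];
    NumericMatrix weights = ob["weights"];
    if (states.ncol() != n || states.nrow() != times.size() ||
        clr.ncol() != n || clr.nrow() != times.size() ||
        weights.ncol() != n || weights.nrow() != times.size())
      stop("observed trajectory dimensions do not match y_bar");
    Observation o;
    o.times.assign(times.begin(), times.end());
    o.states.resize(times.size(), std::vector<double>(n));
    o.clr.resize(times.size(), std::vector<double>(n));
    o.weights.resize(times.size(), std::vector<double>(n));
    for (int t = 0; t < times.size(); ++t)
      for (int i = 0; i < n; ++i) {
        o.states[t][i] = states(t, i);
        o.clr[t][i] = clr(t, i);
        o.weights[t][i] = weights(t, i);
      }
    nobs_total += (times.size() - 1) * n;
    obs.push_back(std::move(o));
  }
  arma::mat A = A0;
  double fx = objective(A, y_bar, y_bar_se_rel, obs, fit_weight, margin,
                        sparsity_weight, nobs_total, w);
  if (!std::isfinite(fx))
    stop("objective must be finite at the starting point");
  // cyclic first-improvement polling: coordinates are visited in
  // row-major order, +step before -step; after an accepted move polling
  // continues with the next coordinate, and the step contracts once a
  // full cycle passes without improvement
  double step = step_init;
  int iters = 0;
  std::vector<double> trace;
  const int nrows = A.n_rows;
  const int ncoord = nrows * n;
  int c = 0, since_improve = 0;
  while (step >= step_tol && iters < max_iters) {
    const int i = c / n, j = c % n;
    bool moved = false;
    for (int d = 0; d < 2; ++d) {
      double delta = (d == 0) ? step : -step;
      double cand = A(i, j) + delta;
      if (diag_constraint && i == j && cand > 0) continue;
      double old = A(i, j);
      A(i, j) = cand;
      double fc = objective(A, y_bar, y_bar_se_rel, obs, fit_weight, margin,
                            sparsity_weight, nobs_total, w);
      if (std::isfinite(fc) && fc < fx) {
        fx = fc;
        moved = true;
        break;
      }
      A(i, j) = old;
    }
    c = (c + 1) % ncoord;
    if (moved) {
      since_improve = 0;
      ++iters;
      trace.push_back(fx);
    } else if (++since_improve == ncoord) {
      step *= step_contract;
      since_improve = 0;
      ++iters;
      trace.push_back(fx);
    }
  }
  return List::create(_["A"] = A, _["value"] = fx, _["iters"] = iters,
                      _["trace"] = trace);
}
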