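// Newton-Raphson statics kernel for tension-only string networks.
// Mirrors the R reference implementation (R/solver.R); the quasi-Newton
// energy fallback for stalled line searches stays on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Material {
  int kind;        // 0 = linear, 1 = tendon (exp toe + linear)
  double E;        // linear modulus
  double a, b, eps_toe, E_linear, sigma_toe;

  double stress(double eps) const {
    if (eps <= 0.0) return 0.0;
    if (kind == 0) return E * eps;
    if (eps <= eps_toe) return a * (std::exp(b * eps) - 1.0);
    return sigma_toe + E_linear * (eps - eps_toe);
  }
  double tangent(double eps) const {
    if (eps < 0.0) return 0.0;
    if (kind == 0) return E;
    if (eps <= eps_toe) return a * b * std::exp(b * eps);
    return E_linear;
  }
};

struct Net {
  int n, m, nf;
  arma::vec x, y, l0, A;
  arma::ivec ei, ej;          // 0-based endpoints
  arma::ivec freeslot;        // node -> free index or -1
  std::vector<int> freenodes; // free slot -> node
  Material mat;
};

struct State {
  arma::vec ux, uy;      // length n
  arma::vec l, eps, N, ex, ey;   // length m
  arma::vec Fx, Fy;      // length n
  double normg;
};

void eval_state(const Net& net, State& st) {
  st.Fx.zeros(net.n);
  st.Fy.zeros(net.n);
  for (int e = 0; e < net.m; ++e) {
    int i = net.ei[e], j = net.ej[e];
    double dx = (net.x[j] + st.ux[j]) - (net.x[i] + st.ux[i]);
    double dy = (net.y[j] + st.uy[j]) - (net.y[i] + st.uy[i]);
    double l = std::sqrt(dx * dx + dy * dy);
    double eps = (l - net.l0[e]) / net.l0[e];
    double N = 0.0, ex = 0.0, ey = 0.0;
    if (l > 0.0) {
      ex = dx / l;
      ey = dy / l;
      if (l >= net.l0[e]) N = net.mat.stress(eps) * net.A[e];
    }
    st.l[e] = l; st.eps[e] = eps; st.N[e] = N; st.ex[e] = ex; st.ey[e] = ey;
    st.Fx[i] -= N * ex; st.Fx[j] += N * ex;
    st.Fy[i] -= N * ey; st.Fy[j] += N * ey;
  }
}

double residual_norm(const Net& net, const State& st, const arma::vec& fx,
                     const arma::vec& fy) {
  double nrm = 0.0;
  for (int k : net.freenodes) {
    nrm = std::max(nrm, std::fabs(st.Fx[k] - fx[k]));
    nrm = std::max(nrm, std::fabs(st.Fy[k] - fy[k]));
  }
  return nrm;
}

// Newton iteration with residual backtracking; returns iterations used.
int newton(const Net& net, const arma::vec& fx, const arma::vec& fy,
           double tol, int max_iter, double floor_k, double step_cap,
           int max_halvings, State& st, bool& converged,
           std::vector<double>& hist) {
  int nf = net.nf;
  st.l.set_size(net.m); st.eps.set_size(net.m); st.N.set_size(net.m);
  st.ex.set_size(net.m); st.ey.set_size(net.m);
  eval_state(net, st);
  st.normg = residual_norm(net, st, fx, fy);
  converged = st.normg <= tol;
  int iter = 0;
  arma::mat K(2 * nf, 2 * nf);
  arma::vec g(2 * nf), dU;
  State trial = st;
  while (!converged && iter < max_iter) {
    ++iter;
    K.zeros();
    for (int e = 0; e < net.m; ++e) {
      if (!(st.l[e] >= net.l0[e]) || st.l[e] <= 0.0) continue;
      double Et = net.mat.tangent(st.eps[e]);
      double km = net.A[e] * Et / net.l0[e];
      double kg = st.N[e] / st.l[e];
      double ex = st.ex[e], ey = st.ey[e];
      double kxx = km * ex * ex + kg * (1.0 - ex * ex);
      double kyy = km * ey * ey + kg * (1.0 - ey * ey);
      double kxy = (km - kg) * ex * ey;
      int fi = net.freeslot[net.ei[e]], fj = net.freeslot[net.ej[e]];
      if (fi >= 0) {
        K(fi, fi) += kxx; K(fi, nf + fi) += kxy;
        K(nf + fi, fi) += kxy; K(nf + fi, nf + fi) += kyy;
      }
      if (fj >= 0) {
        K(fj, fj) += kxx; K(fj, nf + fj) += kxy;
        K(nf + fj, fj) += kxy; K(nf + fj, nf + fj) += kyy;
      }
      if (fi >= 0 && fj >= 0) {
        K(fi, fj) -= kxx; K(fj, fi) -= kxx;
        K(nf + fi, nf + fj) -= kyy; K(nf + fj, nf + fi) -= kyy;
        K(fi, nf + fj) -= kxy; K(nf + fj, fi) -= kxy;
        K(fj, nf + fi) -= kxy; K(nf + fi, fj) -= kxy;
      }
    }
    K.diag() += floor_k;
    for (int s = 0; s < nf; ++s) {
      int k = net.freenodes[s];
      g[s] = st.Fx[k] - fx[k];
      g[nf + s] = st.Fy[k] - fy[k];
    }
    bool ok = arma::solve(dU, K, -g, arma::solve_opts::no_approx);
    if (!ok || !dU.is_finite()) break;
    double s = arma::abs(dU).max();
    if (s > step_cap) dU *= step_cap / s;
    // backtracking line search on the residual norm; keep the best step
    double alpha = 1.0;
    double best_norm = -1.0;
    State best = st;
    for (int h = 0; h < max_halvings; ++h) {
      trial.ux = st.ux; trial.uy = st.uy;
      for (int sidx = 0; sidx < nf; ++sidx) {
        int k = net.freenodes[sidx];
        trial.ux[k] += alpha * dU[sidx];
        trial.uy[k] += alpha * dU[nf + sidx];
      }
      eval_state(net, trial);
      double nrm = residual_norm(net, trial, fx, fy);
      if (std::isfinite(nrm) && (best_norm < 0.0 || nrm < best_norm)) {
        best = trial;
        best_norm = nrm;
      }
      if (std::isfinite(nrm) && nrm < st.normg) break;
      alpha *= 0.5;
    }
    if (best_norm < 0.0 || best_norm >= st.normg) break;   // stalled
    st = best;
    st.normg = best_norm;
    hist.push_back(st.normg);
    converged = st.normg <= tol;
  }
  return iter;
}

Net make_net(const List& cmc) {
  Net net;
  net.x = as<arma::vec>(cmc["x"]);
  net.y = as<arma::vec>(cmc["y"]);
  net.l0 = as<arma::vec>(cmc["l0"]);
  net.A = as<arma::vec>(cmc["A"]);
  net.n = net.x.n_elem;
  net.m = net.l0.n_elem;
  IntegerVector ei = cmc["ei"], ej = cmc["ej"];
  net.ei.set_size(net.m); net.ej.set_size(net.m);
  for (int e = 0; e < net.m; ++e) { net.ei[e] = ei[e] - 1; net.ej[e] = ej[e] - 1; }
  LogicalVector fn = cmc["free_node"];
  net.freeslot.set_size(net.n);
  net.nf = 0;
  for (int k = 0; k < net.n; ++k) {
    if (fn[k]) { net.freeslot[k] = net.nf++; net.freenodes.push_back(k); }
    else net.freeslot[k] = -1;
  }
  List mp = cmc["matpar"];
  net.mat.kind = as<int>(mp["kind"]);
  net.mat.E = as<double>(mp["E"]);
  net.mat.a = as<double>(mp["a"]);
  net.mat.b = as<double>(mp["b"]);
  net.mat.eps_toe = as<double>(mp["eps_toe"]);
  net.mat.E_linear = as<double>(mp["E_linear"]);
  net.mat.sigma_toe = as<double>(mp["sigma_toe"]);
  return net;
}

}  // namespace

// Single solve with full state return; ux0/uy0 give the starting point.
// [[Rcpp::export(name = ".cpp_newton")]]
List cpp_newton(List cmc, NumericVector fx, NumericVector fy,
                double tol, int max_iter, double floor_k, double step_cap,
                int max_halvings, NumericVector ux0, NumericVector uy0) {
  Net net = make_net(cmc);
  State st;
  st.ux = as<arma::vec>(ux0);
  st.uy = as<arma::vec>(uy0);
  arma::vec afx = as<arma::vec>(fx), afy = as<arma::vec>(fy);
  bool converged = false;
  std::vector<double> hist;
  int iter = newton(net, afx, afy, tol, max_iter, floor_k, step_cap,
                    max_halvings, st, converged, hist);
  return List::create(
    _["ux"] = NumericVector(st.ux.begin(), st.ux.end()),
    _["uy"] = NumericVector(st.uy.begin(), st.uy.end()),
    _["converged"] = converged,
    _["iterations"] = iter,
    _["residual_norm"] = st.normg,
    _["residual_history"] = NumericVector(hist.begin(), hist.end()),
    _["N"] = NumericVector(st.N.begin(), st.N.end()),
    _["l"] = NumericVector(st.l.begin(), st.l.end()),
    _["eps"] = NumericVector(st.eps.begin(), st.eps.end()),
    _["Fx"] = NumericVector(st.Fx.begin(), st.Fx.end()),
    _["Fy"] = NumericVector(st.Fy.begin(), st.Fy.end()));
}

// Batch of load sets on one mesh: input tensions -> reactions and
// input-output distances.  Sets whose Newton solve does not converge get
// converged = FALSE (the R side may retry them with the energy fallback).
// [[Rcpp::export(name = ".cpp_simulate_batch")]]
List cpp_simulate_batch(List cmc, NumericMatrix mags, NumericVector angles,
                        IntegerVector input_idx, IntegerVector grounded_idx,
                        double tol, int max_iter, double floor_k,
                        double step_cap, int max_halvings) {
  Net net = make_net(cmc);
  int K = mags.nrow();
  int ni = input_idx.size(), ng = grounded_idx.size();
  NumericMatrix R(K, ng), D(K, ni * ng);
  LogicalVector conv(K);
  arma::vec fx(net.n), fy(net.n);
  std::vector<double> ca(ni), sa(ni);
  for (int a = 0; a < ni; ++a) {
    ca[a] = std::cos(angles[a] * M_PI / 180.0);
    sa[a] = std::sin(angles[a] * M_PI / 180.0);
  }
  for (int k = 0; k < K; ++k) {
    fx.zeros(); fy.zeros();
    for (int a = 0; a < ni; ++a) {
      int node = input_idx[a] - 1;
      fx[node] = mags(k, a) * ca[a];
      fy[node] = mags(k, a) * sa[a];
    }
    State st;
    st.ux.zeros(net.n);
    st.uy.zeros(net.n);
    bool converged = false;
    std::vector<double> hist;
    newton(net, fx, fy, tol, max_iter, floor_k, step_cap, max_halvings,
           st, converged, hist);
    conv[k] = converged;
    if (!converged) continue;
    for (int gi = 0; gi < ng; ++gi) {
      int node = grounded_idx[gi] - 1;
      R(k, gi) = std::sqrt(st.Fx[node] * st.Fx[node] +
                           st.Fy[node] * st.Fy[node]);
    }
    int c = 0;
    for (int a = 0; a < ni; ++a) {
      int ia = input_idx[a] - 1;
      double pxa = net.x[ia] + st.ux[ia], pya = net.y[ia] + st.uy[ia];
      for (int gi = 0; gi < ng; ++gi) {
        int ib = grounded_idx[gi] - 1;
        double dx = pxa - (net.x[ib] + st.ux[ib]);
        double dy = pya - (net.y[ib] + st.uy[ib]);
        D(k, c++) = std::sqrt(dx * dx + dy * dy);
      }
    }
  }
  return List::create(_["R"] = R, _["D"] = D, _["converged"] = conv);
}
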