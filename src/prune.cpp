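// Core likelihood kernels: Felsenstein pruning over site patterns with
// per-node rescaling, and endpoint-conditioned CTMC path sampling for
// stochastic character mapping.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pruning over a postorder edge list.
//   edge:    nedge x 2 (parent, child), ape 1-based ids, postorder
//            (edges sharing a parent are contiguous, children first)
//   P:       cube k x k x (nedge * ncat), slice (e * ncat + c) = P for edge e, cat c
//   tipstate:ntip x npat integer, 1..k observed, 0 missing
//   pi:      root prior; catw: category weights
// Returns per-pattern mixture log-likelihoods.
// [[Rcpp::export]]
arma::vec prune_loglik_cpp(const arma::imat& edge, const arma::cube& P,
                           const arma::imat& tipstate, const arma::vec& pi,
                           const arma::vec& catw, int ntip, int nnode_total) {
  const int nedge = edge.n_rows;
  const int ncat = catw.n_elem;
  const int k = pi.n_elem;
  const int npat = tipstate.n_cols;
  const int root = edge(nedge - 1, 0) - 1;  // last postorder edge's parent

  arma::mat sitell(npat, ncat);
  for (int c = 0; c < ncat; ++c) {
    std::vector<arma::mat> part(nnode_total);
    std::vector<bool> init(nnode_total, false);
    arma::rowvec logscale(npat, arma::fill::zeros);
    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      const arma::mat& Pm = P.slice(e * ncat + c);
      arma::mat contrib(k, npat);
      if (ch < ntip) {
        for (int j = 0; j < npat; ++j) {
          int s = tipstate(ch, j);
          if (s == 0) contrib.col(j) = arma::sum(Pm, 1);  // missing: row sums (=1)
          else contrib.col(j) = Pm.col(s - 1);
        }
      } else {
        contrib = Pm * part[ch];
      }
      if (!init[par]) { part[par] = contrib; init[par] = true; }
      else part[par] %= contrib;
      // parent complete once the next edge has a different parent
      if (e == nedge - 1 || edge(e + 1, 0) - 1 != par) {
        arma::rowvec m = arma::max(part[par], 0);
        for (int j = 0; j < npat; ++j) {
          if (m(j) > 0) { part[par].col(j) /= m(j); logscale(j) += std::log(m(j)); }
          else logscale(j) = -arma::datum::inf;
        }
      }
    }
    arma::rowvec L = pi.t() * part[root];
    for (int j = 0; j < npat; ++j)
      sitell(j, c) = (L(j) > 0 ? std::log(L(j)) : -arma::datum::inf) + logscale(j);
  }
  // mixture over categories in log space
  arma::vec out(npat);
  arma::vec lw = arma::log(catw);
  for (int j = 0; j < npat; ++j) {
    arma::rowvec v = sitell.row(j) + lw.t();
    double m = v.max();
    out(j) = std::isfinite(m) ? m + std::log(arma::sum(arma::exp(v - m))) : m;
  }
  return out;
}

// Forward CTMC simulation from state a over time t; returns final state and
// appends jumps to counts/dwell accumulators only when accepted by caller.
static int simulate_path(const arma::mat& Q, int a, double t,
                         std::vector<int>& states, std::vector<double>& times) {
  const int k = Q.n_rows;
  states.clear(); times.clear();
  int cur = a;
  double s = 0.0;
  while (true) {
    double rate = -Q(cur, cur);
    if (rate <= 0) break;
    double w = R::rexp(1.0 / rate);
    if (s + w >= t) break;
    s += w;
    double u = R::runif(0.0, 1.0) * rate;
    double acc = 0.0;
    int nxt = cur;
    for (int j = 0; j < k; ++j) {
      if (j == cur) continue;
      acc += Q(cur, j);
      if (u <= acc) { nxt = j; break; }
      nxt = j;  // numerical guard: fall through to last state
    }
    states.push_back(nxt); times.push_back(s);
    cur = nxt;
  }
  return cur;
}

// Endpoint-conditioned path sampling for one branch across n histories.
// Rejection sampling (forward simulation until the endpoint matches, up to
// `cap` attempts) with a uniformization fallback.
//   a, b: 1-based endpoint states per history; t branch length.
// Returns: trans (k x k summed jump counts), dwell (k summed), jumps
// (per-history jump count), fallbacks (count of uniformization uses).
// [[Rcpp::export]]
List branch_paths_cpp(const arma::mat& Q, const arma::ivec& a,
                      const arma::ivec& b, double t, int cap) {
  const int k = Q.n_rows;
  const int n = a.n_elem;
  arma::mat trans(k, k, arma::fill::zeros);
  arma::vec dwell(k, arma::fill::zeros);
  arma::ivec jumps(n, arma::fill::zeros);
  int fallbacks = 0;

  // uniformization pieces (built lazily)
  double mu = 0.0;
  arma::mat Rm;
  std::vector<arma::mat> Rpow;
  arma::mat Pt;
  bool unif_ready = false;

  std::vector<int> st; std::vector<double> tm;
  for (int h = 0; h < n; ++h) {
    const int sa = a(h) - 1, sb = b(h) - 1;
    bool ok = false;
    for (int att = 0; att < cap; ++att) {
      int end = simulate_path(Q, sa, t, st, tm);
      if (end == sb) { ok = true; break; }
    }
    if (!ok) {
      // uniformization: sample jump count m | endpoints, then a discrete bridge
      ++fallbacks;
      if (!unif_ready) {
        mu = (-Q.diag()).max() * 1.05 + 1e-12;
        Rm = arma::eye(k, k) + Q / mu;
        Pt = arma::expmat(Q * t);
        Rpow.assign(1, arma::eye(k, k));
        unif_ready = true;
      }
      double denom = std::max(Pt(sa, sb), 1e-300);
      double u = R::runif(0.0, 1.0), acc = 0.0;
      int m = 0;
      const int mmax = 200;
      for (; m <= mmax; ++m) {
        while ((int)Rpow.size() <= m) Rpow.push_back(Rpow.back() * Rm);
        double pm = std::exp(-mu * t + m * std::log(mu * t) - std::lgamma(m + 1.0)) *
                    Rpow[m](sa, sb) / denom;
        acc += pm;
        if (u <= acc) break;
      }
      if (m > mmax) m = mmax;
      while ((int)Rpow.size() <= m) Rpow.push_back(Rpow.back() * Rm);
      // jump times: order statistics of uniforms; states: bridge through R
      arma::vec jt(m);
      for (int i = 0; i < m; ++i) jt(i) = R::runif(0.0, t);
      jt = arma::sort(jt);
      st.clear(); tm.clear();
      int cur = sa;
      for (int i = 0; i < m; ++i) {
        int rem = m - i - 1;
        arma::vec w(k);
        for (int x = 0; x < k; ++x) w(x) = Rm(cur, x) * Rpow[rem](x, sb);
        double tot = arma::sum(w);
        double uu = R::runif(0.0, 1.0) * tot;
        int nxt = k - 1;
        double a2 = 0.0;
        for (int x = 0; x < k; ++x) { a2 += w(x); if (uu <= a2) { nxt = x; break; } }
        if (nxt != cur) { st.push_back(nxt); tm.push_back(jt(i)); }
        cur = nxt;
      }
    }
    // accumulate dwell + transitions
    int cur = sa; double last = 0.0;
    for (size_t i = 0; i < st.size(); ++i) {
      dwell(cur) += tm[i] - last;
      trans(cur, st[i]) += 1.0;
      cur = st[i]; last = tm[i];
    }
    dwell(cur) += t - last;
    jumps(h) = st.size();
  }
  return List::create(_["trans"] = trans, _["dwell"] = dwell,
                      _["jumps"] = jumps, _["fallbacks"] = fallbacks);
}

// Pruning with transition matrices built in-place from the spectral form
// P(t) = V diag(exp(lambda * t * r)) W of a reversible generator; avoids
// R-level P-cube assembly in optimizer inner loops.
// [[Rcpp::export]]
arma::vec prune_loglik_eig_cpp(const arma::imat& edge, const arma::mat& V,
                               const arma::mat& W, const arma::vec& lambda,
                               const arma::vec& lens, const arma::vec& rates,
                               const arma::imat& tipstate, const arma::vec& pi,
                               const arma::vec& catw, int ntip,
                               int nnode_total) {
  const int nedge = edge.n_rows;
  const int ncat = rates.n_elem;
  const int k = pi.n_elem;
  arma::cube P(k, k, nedge * ncat);
  for (int e = 0; e < nedge; ++e)
    for (int c = 0; c < ncat; ++c) {
      arma::vec ex = arma::exp(lambda * lens(e) * rates(c));
      arma::mat Pm = V * (W.each_col() % ex);
      Pm.clamp(0.0, arma::datum::inf);
      Pm.each_col() /= arma::sum(Pm, 1);
      P.slice(e * ncat + c) = Pm;
    }
  return prune_loglik_cpp(edge, P, tipstate, pi, catw, ntip, nnode_total);
}
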