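// Felsenstein pruning over a codon state space, driven by the symmetric
// eigendecomposition of a reversible generator: P(t) = L diag(exp(lambda t)) R.
// Trees arrive as postorder edge lists (ape convention: tips 1..ntip, root
// node ntip+1). Missing leaf states (0) marginalize to a partial vector of
// ones. Per-node rescaling guards against underflow on large trees.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat make_P(const vec& lam, const mat& L, const mat& R, double t) {
  mat P = L * diagmat(exp(lam * t)) * R;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

static inline void rescale_col(vec& v, double& logsc) {
  double m = v.max();
  if (m > 0.0 && (m < 1e-120 || m > 1e120)) {
    v /= m;
    logsc += std::log(m);
  }
}

// Site log-likelihoods for every column, shared rate matrix; branch lengths
// multiplied by `scale`.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_lik_all(const arma::vec& lam, const arma::mat& L,
                                const arma::mat& R, const arma::vec& pi,
                                const arma::imat& edge, const arma::vec& elen,
                                int ntip, int nnode,
                                const arma::imat& states, double scale) {
  const int n = pi.n_elem;
  const int S = states.n_cols;
  const int ntot = ntip + nnode;
  std::vector<mat> down(ntot + 1);
  std::vector<rowvec> sc(ntot + 1);

  for (uword e = 0; e < edge.n_rows; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    mat P = make_P(lam, L, R, elen(e) * scale);
    mat M(n, S);
    if (c <= ntip) {
      for (int s = 0; s < S; ++s) {
        int st = states(c - 1, s);
        if (st <= 0)
          M.col(s).ones();
        else
          M.col(s) = P.col(st - 1);
      }
    } else {
      M = P * down[c];
      down[c].reset();
    }
    if (down[p].n_elem == 0) {
      down[p] = M;
      sc[p] = (c > ntip) ? sc[c] : rowvec(S, fill::zeros);
    } else {
      down[p] %= M;
      if (c > ntip) sc[p] += sc[c];
    }
    // occasional rescale
    rowvec mx = max(down[p], 0);
    for (int s = 0; s < S; ++s) {
      if (mx(s) > 0.0 && (mx(s) < 1e-120 || mx(s) > 1e120)) {
        down[p].col(s) /= mx(s);
        sc[p](s) += std::log(mx(s));
      }
    }
  }
  int root = ntip + 1;
  Rcpp::NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    double v = dot(pi, down[root].col(s));
    out[s] = (v > 0.0) ? std::log(v) + sc[root](s) : R_NegInf;
  }
  return out;
}

// Log-likelihood of a single column; branch lengths multiplied by `scale`
// (the per-site rate multiplier in FEL fits). Uses matrix-vector products
// in the eigenbasis, never forming P explicitly.
// [[Rcpp::export]]
double cpp_lik_site(const arma::vec& lam, const arma::mat& L,
                    const arma::mat& R, const arma::vec& pi,
                    const arma::imat& edge, const arma::vec& elen,
                    int ntip, int nnode,
                    const arma::ivec& col, double scale) {
  const int n = pi.n_elem;
  const int ntot = ntip + nnode;
  std::vector<vec> down(ntot + 1);
  std::vector<double> sc(ntot + 1, 0.0);

  for (uword e = 0; e < edge.n_rows; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    double t = elen(e) * scale;
    vec m;
    bool child_internal = (c > ntip);
    if (!child_internal) {
      int st = col(c - 1);
      if (st <= 0) {
        m = vec(n, fill::ones);
      } else {
        m = L * (exp(lam * t) % R.col(st - 1));
        m.transform([](double x) { return x < 0.0 ? 0.0 : x; });
      }
    } else {
      m = L * (exp(lam * t) % (R * down[c]));
      m.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    }
    if (down[p].n_elem == 0) {
      down[p] = m;
      sc[p] = child_internal ? sc[c] : 0.0;
    } else {
      down[p] %= m;
      if (child_internal) sc[p] += sc[c];
    }
    rescale_col(down[p], sc[p]);
  }
  int root = ntip + 1;
  double v = dot(pi, down[root]);
  return (v > 0.0) ? std::log(v) + sc[root] : R_NegInf;
}

// Batched single-column likelihoods at per-column rate scales.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_lik_sites_scaled(const arma::vec& lam, const arma::mat& L,
                                         const arma::mat& R, const arma::vec& pi,
                                         const arma::imat& edge, const arma::vec& elen,
                                         int ntip, int nnode,
                                         const arma::imat& states,
                                         const arma::vec& scales) {
  const int S = states.n_cols;
  Rcpp::NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    arma::ivec col = states.col(s);
    out[s] = cpp_lik_site(lam, L, R, pi, edge, elen, ntip, nnode, col, scales(s));
  }
  return out;
}

// Edge partials for fast branch-length optimization. For edge e = (p, c),
// A_e holds the likelihood of all data outside the clade of c as a function
// of the state at p (equilibrium frequencies folded in at the root), and
// D_e = down[c]. The edge's log-likelihood as a function of its own length t
// is then sum_s log(A_e(.,s)' P(t) D_e(.,s)) + scales.
// [[Rcpp::export]]
Rcpp::List cpp_edge_partials(const arma::vec& lam, const arma::mat& L,
                             const arma::mat& R, const arma::vec& pi,
                             const arma::imat& edge, const arma::vec& elen,
                             int ntip, int nnode, const arma::imat& states,
                             double scale) {
  const int n = pi.n_elem;
  const int S = states.n_cols;
  const int ntot = ntip + nnode;
  const int nedge = edge.n_rows;

  std::vector<mat> down(ntot + 1);
  std::vector<rowvec> dsc(ntot + 1);
  std::vector<mat> M(nedge);       // P_e * down[child_e]
  std::vector<rowvec> msc(nedge);  // scale carried by M_e
  std::vector<std::vector<int>> kids(ntot + 1);

  // post-order (down) pass
  for (int e = 0; e < nedge; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    kids[p].push_back(e);
    mat P = make_P(lam, L, R, elen(e) * scale);
    if (c <= ntip) {
      mat Mc(n, S);
      for (int s = 0; s < S; ++s) {
        int st = states(c - 1, s);
        if (st <= 0)
          Mc.col(s).ones();
        else
          Mc.col(s) = P.col(st - 1);
      }
      M[e] = Mc;
      msc[e] = rowvec(S, fill::zeros);
      // keep leaf down partial (indicator) for the edge list
      mat leafD(n, S, fill::zeros);
      for (int s = 0; s < S; ++s) {
        int st = states(c - 1, s);
        if (st <= 0)
          leafD.col(s).ones();
        else
          leafD(st - 1, s) = 1.0;
      }
      down[c] = leafD;
      dsc[c] = rowvec(S, fill::zeros);
    } else {
      M[e] = P * down[c];
      msc[e] = dsc[c];
    }
    if (down[p].n_elem == 0) {
      down[p] = M[e];
      dsc[p] = msc[e];
    } else {
      down[p] %= M[e];
      dsc[p] += msc[e];
    }
    rowvec mx = max(down[p], 0);
    for (int s = 0; s < S; ++s) {
      if (mx(s) > 0.0 && (mx(s) < 1e-120 || mx(s) > 1e120)) {
        down[p].col(s) /= mx(s);
        dsc[p](s) += std::log(mx(s));
      }
    }
  }

  int root = ntip + 1;
  std::vector<mat> B(ntot + 1);
  std::vector<rowvec> bsc(ntot + 1);
  B[root] = repmat(pi, 1, S);
  bsc[root] = rowvec(S, fill::zeros);

  Rcpp::List A_out(nedge), D_out(nedge), asc_out(nedge), dsc_out(nedge);

  // pre-order (up) pass: reverse postorder visits parents before children
  for (int e = nedge - 1; e >= 0; --e) {
    int p = edge(e, 0), c = edge(e, 1);
    mat A = B[p];
    rowvec asc = bsc[p];
    for (int j : kids[p]) {
      if (j == e) continue;
      A %= M[j];
      asc += msc[j];
    }
    rowvec mx = max(A, 0);
    for (int s = 0; s < S; ++s) {
      if (mx(s) > 0.0 && (mx(s) < 1e-120 || mx(s) > 1e120)) {
        A.col(s) /= mx(s);
        asc(s) += std::log(mx(s));
      }
    }
    A_out[e] = A;
    asc_out[e] = asc;
    D_out[e] = down[c];
    dsc_out[e] = dsc[c];
    if (c > ntip) {
      mat P = make_P(lam, L, R, elen(e) * scale);
      B[c] = P.t() * A;
      bsc[c] = asc;
      rowvec bx = max(B[c], 0);
      for (int s = 0; s < S; ++s) {
        if (bx(s) > 0.0 && (bx(s) < 1e-120 || bx(s) > 1e120)) {
          B[c].col(s) /= bx(s);
          bsc[c](s) += std::log(bx(s));
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = A_out,
                            Rcpp::Named("A_scale") = asc_out,
                            Rcpp::Named("D") = D_out,
                            Rcpp::Named("D_scale") = dsc_out);
}

// Total log-likelihood seen across one edge, as a function of its length.
// [[Rcpp::export]]
double cpp_edge_loglik(const arma::vec& lam, const arma::mat& L,
                       const arma::mat& R, const arma::mat& A,
                       const arma::rowvec& A_scale, const arma::mat& D,
                       const arma::rowvec& D_scale, double t) {
  mat P = make_P(lam, L, R, t);
  mat W = P * D;
  rowvec per = sum(A % W, 0);
  double ll = 0.0;
  for (uword s = 0; s < per.n_elem; ++s) {
    if (per(s) <= 0.0) return R_NegInf;
    ll += std::log(per(s)) + A_scale(s) + D_scale(s);
  }
  return ll;
}
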