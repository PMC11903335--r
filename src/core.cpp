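// Compiled kernels for chain alignment and TM-score search.
// Coordinate matrices are n x 3 (rows = residues), transforms map
// target coordinates into the query frame: x -> R * x + t.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Rigid {
  arma::mat R;
  arma::vec t;
  double rmsd;
};

// Least-squares superposition of T onto Q (Kabsch via SVD).
static Rigid kabsch_core(const arma::mat &Q, const arma::mat &T) {
  arma::rowvec qc = arma::mean(Q, 0);
  arma::rowvec tc = arma::mean(T, 0);
  arma::mat Qc = Q.each_row() - qc;
  arma::mat Tc = T.each_row() - tc;
  arma::mat A = Tc.t() * Qc;  // 3x3 cross-covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, A)) stop("SVD failed in Kabsch superposition");
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0.0) ? -1.0 : 1.0;  // enforce a proper rotation
  Rigid out;
  out.R = V * D * U.t();
  out.t = qc.t() - out.R * tc.t();
  arma::mat Tfit = (out.R * T.t()).t();
  Tfit.each_row() += out.t.t();
  out.rmsd = std::sqrt(arma::accu(arma::square(Q - Tfit)) / Q.n_rows);
  return out;
}

static arma::mat apply_rigid(const Rigid &rt, const arma::mat &X) {
  arma::mat Y = (rt.R * X.t()).t();
  Y.each_row() += rt.t.t();
  return Y;
}

// [[Rcpp::export(name = ".kabsch_cpp")]]
List kabsch_cpp(const arma::mat &Q, const arma::mat &T) {
  Rigid rt = kabsch_core(Q, T);
  return List::create(_["rotation"] = rt.R, _["translation"] = rt.t,
                      _["rmsd"] = rt.rmsd);
}

// Gotoh global DP with free end gaps, gap open penalty, no extension
// penalty. Returns 1-based aligned index pairs, strictly increasing in
// both coordinates. Tie-break: diagonal > up > left (deterministic).
static arma::umat dp_core(const arma::mat &S, double gap_open) {
  const int n = S.n_rows, m = S.n_cols;
  const double NEG = -1e30;
  arma::mat H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  // trace codes: 0 diag, 1 up (gap in target), 2 left (gap in query)
  arma::Mat<unsigned char> TB(n + 1, m + 1, arma::fill::zeros);
  H.row(0).zeros();
  H.col(0).zeros();  // free end gaps
  E.col(0).fill(NEG);
  E.row(0).fill(NEG);
  F.col(0).fill(NEG);
  F.row(0).fill(NEG);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) + gap_open, E(i, j - 1));
      F(i, j) = std::max(H(i - 1, j) + gap_open, F(i - 1, j));
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double best = diag;
      unsigned char tb = 0;
      if (F(i, j) > best) { best = F(i, j); tb = 1; }
      if (E(i, j) > best) { best = E(i, j); tb = 2; }
      H(i, j) = best;
      TB(i, j) = tb;
    }
  }
  // best cell on the last row or column (free end gaps)
  int bi = n, bj = m;
  double best = H(n, m);
  for (int j = 0; j <= m; ++j)
    if (H(n, j) > best) { best = H(n, j); bi = n; bj = j; }
  for (int i = 0; i <= n; ++i)
    if (H(i, m) > best) { best = H(i, m); bi = i; bj = m; }
  std::vector<unsigned int> qi, tj;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    unsigned char tb = TB(i, j);
    if (tb == 0) {
      qi.push_back(i);
      tj.push_back(j);
      --i; --j;
    } else if (tb == 1) {
      --i;
    } else {
      --j;
    }
  }
  arma::umat pairs(qi.size(), 2);
  for (size_t k = 0; k < qi.size(); ++k) {
    pairs(k, 0) = qi[qi.size() - 1 - k];
    pairs(k, 1) = tj[qi.size() - 1 - k];
  }
  return pairs;
}

// [[Rcpp::export(name = ".dp_align_cpp")]]
IntegerMatrix dp_align_cpp(const arma::mat &S, double gap_open) {
  arma::umat p = dp_core(S, gap_open);
  IntegerMatrix out(p.n_rows, 2);
  for (arma::uword k = 0; k < p.n_rows; ++k) {
    out(k, 0) = p(k, 0);
    out(k, 1) = p(k, 1);
  }
  return out;
}

static double pair_score(const arma::mat &Q, const arma::mat &Tt,
                         const arma::umat &pairs, double d0) {
  double s = 0.0;
  for (arma::uword k = 0; k < pairs.n_rows; ++k) {
    arma::rowvec d = Q.row(pairs(k, 0) - 1) - Tt.row(pairs(k, 1) - 1);
    s += 1.0 / (1.0 + arma::dot(d, d) / (d0 * d0));
  }
  return s;
}

// Iterative refinement from one seed superposition: score all residue
// pairs as 1/(1 + (d/d0)^2), realign by DP, re-superpose on the new
// pair set. A step is accepted only if the alignment score does not
// decrease, so the per-seed score trace is non-decreasing.
// [[Rcpp::export(name = ".align_refine_cpp")]]
List align_refine_cpp(const arma::mat &Q, const arma::mat &T,
                      const arma::mat &R0, const arma::vec &t0, double d0,
                      double gap_open, int max_iters) {
  Rigid cur;
  cur.R = R0;
  cur.t = t0;
  arma::umat best_pairs;
  Rigid best = cur;
  double best_score = -1.0;
  std::vector<double> trace;
  const double d0sq = d0 * d0;
  for (int iter = 0; iter < max_iters; ++iter) {
    arma::mat Tt = apply_rigid(cur, T);
    arma::mat S(Q.n_rows, T.n_rows);
    for (arma::uword i = 0; i < Q.n_rows; ++i)
      for (arma::uword j = 0; j < T.n_rows; ++j) {
        arma::rowvec d = Q.row(i) - Tt.row(j);
        S(i, j) = 1.0 / (1.0 + arma::dot(d, d) / d0sq);
      }
    arma::umat pairs = dp_core(S, gap_open);
    if (pairs.n_rows < 3) break;
    arma::mat Qs(pairs.n_rows, 3), Ts(pairs.n_rows, 3);
    for (arma::uword k = 0; k < pairs.n_rows; ++k) {
      Qs.row(k) = Q.row(pairs(k, 0) - 1);
      Ts.row(k) = T.row(pairs(k, 1) - 1);
    }
    Rigid rt = kabsch_core(Qs, Ts);
    arma::mat Tfit = apply_rigid(rt, T);
    double score = pair_score(Q, Tfit, pairs, d0);
    if (score <= best_score + 1e-12) break;  // no improvement: keep previous
    bool same = (best_pairs.n_rows == pairs.n_rows) &&
                arma::all(arma::vectorise(best_pairs) == arma::vectorise(pairs));
    best_pairs = pairs;
    best = rt;
    best_score = score;
    trace.push_back(score);
    cur = rt;
    if (same) break;  // pair set stable
  }
  if (best_score < 0.0)
    return List::create(_["ok"] = false);
  IntegerMatrix out(best_pairs.n_rows, 2);
  for (arma::uword k = 0; k < best_pairs.n_rows; ++k) {
    out(k, 0) = best_pairs(k, 0);
    out(k, 1) = best_pairs(k, 1);
  }
  return List::create(_["ok"] = true, _["pairs"] = out,
                      _["rotation"] = best.R, _["translation"] = best.t,
                      _["score"] = best_score,
                      _["score_trace"] = NumericVector(trace.begin(), trace.end()));
}

// TM-score superposition search over paired coordinates. Seeds from
// contiguous alignment fragments of lengths La, La/2, La/4 at stride
// max(1, La/10); each seed is refined by iterating Kabsch on the pairs
// closer than max(d0, 4.5) A until the subset is stable. Returns the
// maximal unnormalized sum  sum_i 1/(1 + (d_i/d0)^2)  and its transform.
// [[Rcpp::export(name = ".tm_search_cpp")]]
List tm_search_cpp(const arma::mat &Qp, const arma::mat &Tp, double d0) {
  const int n = Qp.n_rows;
  if (n < 3) stop("TM-score search needs at least 3 aligned pairs");
  const double dcut = std::max(d0, 4.5);
  const double dcut_sq = dcut * dcut, d0sq = d0 * d0;
  int stride = std::max(1, n / 10);
  std::vector<int> lens;
  for (int l : {n, n / 2, n / 4})
    if (l >= 3 && (lens.empty() || l != lens.back())) lens.push_back(l);
  double best_sum = -1.0;
  Rigid best;
  for (int l : lens) {
    for (int s = 0; s + l <= n; s += stride) {
      arma::uvec sub = arma::regspace<arma::uvec>(s, s + l - 1);
      for (int iter = 0; iter < 30; ++iter) {
        Rigid rt = kabsch_core(Qp.rows(sub), Tp.rows(sub));
        arma::mat Tt = apply_rigid(rt, Tp);
        arma::vec d2 = arma::sum(arma::square(Qp - Tt), 1);
        double sum = arma::accu(1.0 / (1.0 + d2 / d0sq));
        if (sum > best_sum) {
          best_sum = sum;
          best = rt;
        }
        arma::uvec nsub = arma::find(d2 < dcut_sq);
        if (nsub.n_elem < 3 ||
            (nsub.n_elem == sub.n_elem && arma::all(nsub == sub)))
          break;
        sub = nsub;
      }
      if (l == n) break;  // full-length fragment has a single placement
    }
  }
  return List::create(_["sum"] = best_sum, _["rotation"] = best.R,
                      _["translation"] = best.t);
}
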