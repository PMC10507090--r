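// Numerical core: Spearman correlation, PSD repair, graphical lasso with
// EBIC path selection, permutation null loops for the network comparison
// test, and the signed spinglass annealer. All R-facing wrappers live in R/.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------- ranks ----

// average (mid-) ranks, the standard Spearman convention for ties
static arma::vec rank_avg(const arma::vec& x) {
  const arma::uword n = x.n_elem;
  arma::uvec ord = arma::stable_sort_index(x);
  arma::vec r(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && x(ord(j + 1)) == x(ord(i))) ++j;
    const double avg = 0.5 * (double)(i + j) + 1.0;
    for (arma::uword k = i; k <= j; ++k) r(ord(k)) = avg;
    i = j + 1;
  }
  return r;
}

// [[Rcpp::export]]
arma::mat cpp_rank_columns(const arma::mat& X) {
  arma::mat R(X.n_rows, X.n_cols);
  for (arma::uword j = 0; j < X.n_cols; ++j) R.col(j) = rank_avg(X.col(j));
  return R;
}

// [[Rcpp::export]]
arma::mat cpp_spearman(const arma::mat& X) {
  arma::mat C = arma::cor(cpp_rank_columns(X));
  C = 0.5 * (C + C.t());
  C.diag().ones();
  return C;
}

// ------------------------------------------------------------ PSD repair ---

// eigenvalue clipping at zero followed by renormalization to a correlation
// matrix; inputs already PSD (min eigenvalue >= -tol) are returned unchanged
// so the operation is exactly idempotent
// [[Rcpp::export]]
List cpp_psd_clip(const arma::mat& R, double tol) {
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, arma::symmatu(R));
  const double mineig = eval.min();
  if (mineig >= -tol) {
    return List::create(_["matrix"] = R, _["min_eig_before"] = mineig,
                        _["changed"] = false);
  }
  arma::vec ec = arma::clamp(eval, 0.0, arma::datum::inf);
  arma::mat A = evec * arma::diagmat(ec) * evec.t();
  arma::vec d = A.diag();
  for (arma::uword i = 0; i < d.n_elem; ++i)
    d(i) = (d(i) > 1e-12) ? 1.0 / std::sqrt(d(i)) : 0.0;
  A = arma::diagmat(d) * A * arma::diagmat(d);
  A = 0.5 * (A + A.t());
  A.diag().ones();
  return List::create(_["matrix"] = A, _["min_eig_before"] = mineig,
                      _["changed"] = true);
}

// --------------------------------------------------------------- glasso ----

// one glasso solve by block coordinate descent on the covariance W
// (Friedman-style; off-diagonal penalty only, diagonal of W fixed at S).
// W and B carry warm starts across a penalty path.
static bool glasso_core(const arma::mat& S, double lambda, arma::mat& W,
                        arma::mat& B, arma::mat& Theta, double tol,
                        int maxit, int& iters) {
  const int p = (int)S.n_rows;
  double offavg = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) offavg += std::fabs(S(i, j));
  offavg /= std::max(1, p * (p - 1));
  const double thr = tol * (offavg > 0 ? offavg : 1.0);
  const double inner_thr = 0.1 * thr;
  arma::vec tmp(p);

  bool conv = false;
  for (iters = 1; iters <= maxit; ++iters) {
    double dw = 0.0;
    for (int j = 0; j < p; ++j) {
      // lasso sub-problem for column j: min .5 b'W11 b - s12'b + lambda|b|_1
      // maintained residual: tmp = W * B(,j)  (B(j,j) == 0, entry j unused)
      tmp = W * B.col(j);
      for (int sweep = 0; sweep < 1000; ++sweep) {
        double dlx = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          const double old = B(k, j);
          const double r = S(k, j) - tmp(k) + W(k, k) * old;
          double bn = 0.0;
          if (lambda > 0.0) {
            if (r > lambda) bn = (r - lambda) / W(k, k);
            else if (r < -lambda) bn = (r + lambda) / W(k, k);
          } else {
            bn = r / W(k, k);
          }
          if (bn != old) {
            B(k, j) = bn;
            tmp += (bn - old) * W.col(k);
            const double d = std::fabs(bn - old);
            if (d > dlx) dlx = d;
          }
        }
        if (dlx < inner_thr) break;
      }
      // w12 = W11 * beta == tmp (entries k != j)
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        const double d = std::fabs(tmp(k) - W(k, j));
        if (d > dw) dw = d;
        W(k, j) = tmp(k);
        W(j, k) = tmp(k);
      }
    }
    if (dw < thr) { conv = true; break; }
  }

  // back out the precision matrix from the partitioned inverse identities
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int l = 0; l < p; ++l) {
      if (l == j) continue;
      dot += W(l, j) * B(l, j);
    }
    const double tjj = 1.0 / (W(j, j) - dot);
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -B(k, j) * tjj;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());
  return conv;
}

static arma::mat partials_from_precision(const arma::mat& Th) {
  arma::vec d = Th.diag();
  for (arma::uword i = 0; i < d.n_elem; ++i) d(i) = 1.0 / std::sqrt(d(i));
  arma::mat Wp = -(arma::diagmat(d) * Th * arma::diagmat(d));
  Wp = 0.5 * (Wp + Wp.t());
  Wp.diag().zeros();
  return Wp;
}

// [[Rcpp::export]]
List cpp_glasso(const arma::mat& S, double lambda, double tol, int maxit) {
  const int p = (int)S.n_rows;
  arma::mat Theta(p, p, arma::fill::zeros);
  if (lambda <= 0.0) {
    // unpenalized problem: exact maximum-likelihood solution is the inverse
    arma::mat Th;
    const bool ok = arma::inv_sympd(Th, arma::symmatu(S));
    if (!ok) stop("glasso with lambda = 0 requires a positive definite correlation matrix");
    return List::create(_["precision"] = Th, _["covariance"] = S,
                        _["iterations"] = 0, _["converged"] = true);
  }
  arma::mat W = arma::symmatu(S);
  arma::mat B(p, p, arma::fill::zeros);
  int iters = 0;
  const bool conv = glasso_core(S, lambda, W, B, Theta, tol, maxit, iters);
  if (!conv)
    stop("glasso did not converge in %d iterations (lambda = %g)", maxit, lambda);
  return List::create(_["precision"] = Theta, _["covariance"] = W,
                      _["iterations"] = iters, _["converged"] = conv);
}

// EBIC along a decreasing lambda path with warm starts; ties on the EBIC
// minimum resolve to the larger lambda (sparser model) because only strict
// improvement replaces the incumbent
// [[Rcpp::export]]
List cpp_glasso_path(const arma::mat& S, int n, double gamma,
                     const arma::vec& lambdas, double tol, int maxit,
                     double edge_tol) {
  const int p = (int)S.n_rows;
  const int L = (int)lambdas.n_elem;
  arma::mat W = arma::symmatu(S);
  arma::mat B(p, p, arma::fill::zeros);
  arma::mat Theta(p, p, arma::fill::zeros);
  arma::vec ebics(L);
  arma::ivec ecounts(L);
  arma::mat bestTheta;
  double bestEbic = arma::datum::inf;
  int bestIdx = -1;

  for (int t = 0; t < L; ++t) {
    int iters = 0;
    const bool conv = glasso_core(S, lambdas(t), W, B, Theta, tol, maxit, iters);
    if (!conv)
      stop("glasso did not converge in %d iterations (lambda = %g, path step %d)",
           maxit, lambdas(t), t + 1);
    int E = 0;
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j)
        if (std::fabs(Theta(i, j)) > edge_tol) ++E;
    double ld;
    const bool ok = arma::log_det_sympd(ld, arma::symmatu(Theta));
    if (!ok) stop("estimated precision matrix is not positive definite");
    const double trS = arma::accu(S % Theta);
    const double ll = 0.5 * (double)n * (ld - trS);
    const double eb = -2.0 * ll + (double)E * std::log((double)n) +
                      4.0 * (double)E * gamma * std::log((double)p);
    ebics(t) = eb;
    ecounts(t) = E;
    if (eb < bestEbic) {
      bestEbic = eb;
      bestIdx = t;
      bestTheta = Theta;
    }
  }
  return List::create(_["weights"] = partials_from_precision(bestTheta),
                      _["precision"] = bestTheta,
                      _["ebics"] = ebics,
                      _["edge_counts"] = ecounts,
                      _["best_index"] = bestIdx + 1);
}

// ------------------------------------------- fast estimator (no missing) ---

static arma::vec make_lambdas(const arma::mat& C, int nlambda,
                              double min_ratio, double lambda_floor) {
  double lmax = 0.0;
  const int p = (int)C.n_rows;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j)
      lmax = std::max(lmax, std::fabs(C(i, j)));
  if (lmax < lambda_floor) lmax = lambda_floor;
  arma::vec lam = arma::exp(arma::linspace(std::log(lmax),
                                           std::log(lmax * min_ratio), nlambda));
  return lam;
}

static arma::mat estimate_weights_internal(const arma::mat& X, double gamma,
                                           int nlambda, double min_ratio,
                                           double lambda_floor, double tol,
                                           int maxit, double edge_tol) {
  arma::mat C = cpp_spearman(X);
  // PSD repair inline (same rule as cpp_psd_clip)
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, C);
  if (eval.min() < -1e-8) {
    arma::vec ec = arma::clamp(eval, 0.0, arma::datum::inf);
    arma::mat A = evec * arma::diagmat(ec) * evec.t();
    arma::vec d = A.diag();
    for (arma::uword i = 0; i < d.n_elem; ++i)
      d(i) = (d(i) > 1e-12) ? 1.0 / std::sqrt(d(i)) : 0.0;
    C = arma::diagmat(d) * A * arma::diagmat(d);
    C = 0.5 * (C + C.t());
    C.diag().ones();
  }
  arma::vec lam = make_lambdas(C, nlambda, min_ratio, lambda_floor);
  const int p = (int)C.n_rows;
  arma::mat W = C, B(p, p, arma::fill::zeros), Theta(p, p, arma::fill::zeros);
  arma::mat bestTheta;
  double bestEbic = arma::datum::inf;
  const int n = (int)X.n_rows;
  for (int t = 0; t < (int)lam.n_elem; ++t) {
    int iters = 0;
    if (!glasso_core(C, lam(t), W, B, Theta, tol, maxit, iters))
      stop("glasso did not converge (lambda = %g)", lam(t));
    int E = 0;
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j)
        if (std::fabs(Theta(i, j)) > edge_tol) ++E;
    double ld;
    if (!arma::log_det_sympd(ld, arma::symmatu(Theta)))
      stop("estimated precision matrix is not positive definite");
    const double ll = 0.5 * (double)n * (ld - arma::accu(C % Theta));
    const double eb = -2.0 * ll + (double)E * std::log((double)n) +
                      4.0 * (double)E * gamma * std::log((double)p);
    if (eb < bestEbic) { bestEbic = eb; bestTheta = Theta; }
  }
  return partials_from_precision(bestTheta);
}

// [[Rcpp::export]]
arma::mat cpp_estimate_weights(const arma::mat& X, double gamma, int nlambda,
                               double min_ratio, double lambda_floor,
                               double tol, int maxit, double edge_tol) {
  return estimate_weights_internal(X, gamma, nlambda, min_ratio, lambda_floor,
                                   tol, maxit, edge_tol);
}

// ----------------------------------------------------------- NCT nulls -----

static double global_strength_of(const arma::mat& W) {
  double s = 0.0;
  for (arma::uword i = 0; i < W.n_rows; ++i)
    for (arma::uword j = i + 1; j < W.n_cols; ++j)
      s += std::fabs(W(i, j));
  return s;
}

static void record_stats(const arma::mat& WA, const arma::mat& WB, int b,
                         arma::vec& Snull, arma::vec& Mnull, arma::mat& sdiff,
                         arma::mat& ediff) {
  const int p = (int)WA.n_rows;
  Snull(b) = std::fabs(global_strength_of(WA) - global_strength_of(WB));
  arma::mat D = arma::abs(WA - WB);
  Mnull(b) = D.max();
  arma::vec sA = arma::sum(arma::abs(WA), 1);
  arma::vec sB = arma::sum(arma::abs(WB), 1);
  for (int i = 0; i < p; ++i) sdiff(b, i) = std::fabs(sA(i) - sB(i));
  int t = 0;
  for (int j = 1; j < p; ++j)
    for (int i = 0; i < j; ++i) ediff(b, t++) = D(i, j);
}

// independent design: perm holds 1-based row permutations of the pooled data;
// the first nA permuted rows form group A
// [[Rcpp::export]]
List cpp_nct_null_independent(const arma::mat& Xpool, int nA,
                              const arma::imat& perm, double gamma,
                              int nlambda, double min_ratio,
                              double lambda_floor, double tol, int maxit,
                              double edge_tol) {
  const int n = (int)Xpool.n_rows, p = (int)Xpool.n_cols;
  const int nperm = (int)perm.n_cols;
  const int ne = p * (p - 1) / 2;
  arma::vec Snull(nperm), Mnull(nperm);
  arma::mat sdiff(nperm, p), ediff(nperm, ne);
  for (int b = 0; b < nperm; ++b) {
    if (b % 50 == 0) Rcpp::checkUserInterrupt();
    arma::uvec idx(n);
    for (int i = 0; i < n; ++i) idx(i) = (arma::uword)(perm(i, b) - 1);
    arma::mat Xp = Xpool.rows(idx);
    arma::mat WA = estimate_weights_internal(Xp.rows(0, nA - 1), gamma,
                                             nlambda, min_ratio, lambda_floor,
                                             tol, maxit, edge_tol);
    arma::mat WB = estimate_weights_internal(Xp.rows(nA, n - 1), gamma,
                                             nlambda, min_ratio, lambda_floor,
                                             tol, maxit, edge_tol);
    record_stats(WA, WB, b, Snull, Mnull, sdiff, ediff);
  }
  return List::create(_["S_null"] = Snull, _["M_null"] = Mnull,
                      _["strength_diff"] = sdiff, _["edge_diff"] = ediff);
}

// paired design: swap(i, b) == 1 exchanges subject i's two condition rows
// [[Rcpp::export]]
List cpp_nct_null_paired(const arma::mat& Xa, const arma::mat& Xb,
                         const arma::imat& swap, double gamma, int nlambda,
                         double min_ratio, double lambda_floor, double tol,
                         int maxit, double edge_tol) {
  const int n = (int)Xa.n_rows, p = (int)Xa.n_cols;
  const int nperm = (int)swap.n_cols;
  const int ne = p * (p - 1) / 2;
  arma::vec Snull(nperm), Mnull(nperm);
  arma::mat sdiff(nperm, p), ediff(nperm, ne);
  arma::mat XA(n, p), XB(n, p);
  for (int b = 0; b < nperm; ++b) {
    if (b % 50 == 0) Rcpp::checkUserInterrupt();
    for (int i = 0; i < n; ++i) {
      if (swap(i, b) == 1) {
        XA.row(i) = Xb.row(i);
        XB.row(i) = Xa.row(i);
      } else {
        XA.row(i) = Xa.row(i);
        XB.row(i) = Xb.row(i);
      }
    }
    arma::mat WA = estimate_weights_internal(XA, gamma, nlambda, min_ratio,
                                             lambda_floor, tol, maxit, edge_tol);
    arma::mat WB = estimate_weights_internal(XB, gamma, nlambda, min_ratio,
                                             lambda_floor, tol, maxit, edge_tol);
    record_stats(WA, WB, b, Snull, Mnull, sdiff, ediff);
  }
  return List::create(_["S_null"] = Snull, _["M_null"] = Mnull,
                      _["strength_diff"] = sdiff, _["edge_diff"] = ediff);
}

// ------------------------------------------------------------ spinglass ----

// coupling matrix of the signed Potts Hamiltonian: positive and negative
// layers each against their own configuration-model null
static arma::mat spin_coupling(const arma::mat& W, double gpos, double gneg) {
  const int p = (int)W.n_rows;
  arma::mat Wp(p, p, arma::fill::zeros), Wn(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) {
      if (i == j) continue;
      if (W(i, j) > 0) Wp(i, j) = W(i, j);
      else if (W(i, j) < 0) Wn(i, j) = -W(i, j);
    }
  arma::vec sp = arma::sum(Wp, 1), sn = arma::sum(Wn, 1);
  const double mp = arma::accu(sp) / 2.0, mn = arma::accu(sn) / 2.0;
  arma::mat J = Wp;
  if (mp > 0) J -= gpos * (sp * sp.t()) / (2.0 * mp);
  J -= Wn;
  if (mn > 0) J += gneg * (sn * sn.t()) / (2.0 * mn);
  J.diag().zeros();
  return J;
}

static double spin_energy_of(const arma::mat& J, const arma::ivec& lab) {
  double H = 0.0;
  const int p = (int)J.n_rows;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j)
      if (lab(i) == lab(j)) H -= J(i, j);
  return H;
}

// [[Rcpp::export]]
double cpp_spin_energy(const arma::mat& W, const arma::ivec& labels,
                       double gpos, double gneg) {
  return spin_energy_of(spin_coupling(W, gpos, gneg), labels);
}

// simulated annealing on the signed Potts Hamiltonian; uses R's RNG so a
// set.seed() in the caller makes the run deterministic. Returns the best
// labeling visited with its exactly recomputed energy.
// [[Rcpp::export]]
List cpp_spinglass(const arma::mat& W, int max_spins, double gpos,
                   double gneg, double t0, double tmin, double cool) {
  const int p = (int)W.n_rows;
  arma::mat J = spin_coupling(W, gpos, gneg);
  arma::ivec lab(p);
  for (int i = 0; i < p; ++i) {
    int s = 1 + (int)(unif_rand() * max_spins);
    if (s > max_spins) s = max_spins;
    lab(i) = s;
  }
  double E = spin_energy_of(J, lab);
  arma::ivec best = lab;
  double Ebest = E;
  for (double T = t0; T >= tmin; T *= cool) {
    for (int v = 0; v < p; ++v) {
      int cand = 1 + (int)(unif_rand() * max_spins);
      if (cand > max_spins) cand = max_spins;
      const int cur = lab(v);
      if (cand == cur) continue;
      double Acur = 0.0, Acand = 0.0;
      for (int u = 0; u < p; ++u) {
        if (u == v) continue;
        if (lab(u) == cur) Acur += J(v, u);
        else if (lab(u) == cand) Acand += J(v, u);
      }
      const double dE = Acur - Acand;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / T)) {
        lab(v) = cand;
        E += dE;
        if (E < Ebest) { Ebest = E; best = lab; }
      }
    }
  }
  return List::create(_["labels"] = best,
                      _["energy"] = spin_energy_of(J, best));
}
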