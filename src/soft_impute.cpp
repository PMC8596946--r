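// SOFT-IMPUTE inner loop: iterative soft-thresholded SVD on the
// observed-filled matrix, with the fit kept in factored form (W B) so each
// sweep only touches the missing entries. The SVD is taken on the small
// side: for M (n x p, n <= p), G = M M^T = U D^2 U^T and the thresholded
// reconstruction is Z = [U_r diag((d - lambda)/d)] [U_r^T M]. Missing
// entries are regenerated per sweep in column runs that share the same
// missing-row set (one small GEMM per run), which matches the
// whole-session-block missingness of the subject x (session, voxel) data.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct MissRun {            // columns [c0, c1] all missing exactly rows `rows`
  uword c0, c1;
  uvec rows;
  uvec cols;                // regspace c0..c1, cached for submat assignment
};

// [[Rcpp::export]]
Rcpp::List soft_impute_core(const arma::mat& X, const arma::uvec& miss,
                            double lambda, double tol, int max_iter,
                            int max_rank, const arma::mat& warm,
                            bool has_warm, bool track_objective) {
  const uword n = X.n_rows, p = X.n_cols;
  const bool wide = n <= p;

  // work in the wide orientation throughout
  mat M = wide ? X : X.t();
  const uword nr = M.n_rows, nc = M.n_cols;

  // missing rows per (wide-orientation) column, then runs of equal pattern
  std::vector<std::vector<uword>> col_rows(nc);
  for (uword k = 0; k < miss.n_elem; ++k) {
    uword idx = miss(k);
    uword i = idx % n, j = idx / n;
    if (wide) col_rows[j].push_back(i);
    else col_rows[i].push_back(j);
  }
  std::vector<MissRun> runs;
  for (uword c = 0; c < nc; ++c) {
    if (col_rows[c].empty()) continue;
    if (!runs.empty() && runs.back().c1 == c - 1 &&
        runs.back().rows.n_elem == col_rows[c].size() &&
        std::equal(col_rows[c].begin(), col_rows[c].end(),
                   runs.back().rows.begin())) {
      runs.back().c1 = c;
    } else {
      MissRun r;
      r.c0 = r.c1 = c;
      r.rows = uvec(col_rows[c]);
      runs.push_back(r);
    }
  }
  for (auto& r : runs) r.cols = regspace<uvec>(r.c0, r.c1);

  // initialize missing entries
  for (auto& r : runs) {
    for (uword c = r.c0; c <= r.c1; ++c)
      for (uword q = 0; q < r.rows.n_elem; ++q)
        M(r.rows(q), c) = has_warm
          ? (wide ? warm(r.rows(q), c) : warm(c, r.rows(q)))
          : 0.0;
  }

  mat W_old, B_old;
  double normZ2_old = 0.0;
  bool have_old = false;
  std::vector<double> objective;
  vec d_keep(nr, fill::zeros);
  int rank = 0;
  bool converged = false;
  int it = 0;
  mat W, B;                 // Z = W * B in wide orientation

  while (it < max_iter) {
    ++it;
    mat G = M * M.t();      // nr x nr
    vec eval;
    mat evec;
    eig_sym(eval, evec, G); // ascending
    vec d(nr), dnew(nr);
    for (uword i = 0; i < nr; ++i) {
      double e = eval(nr - 1 - i);
      d(i) = e > 0 ? std::sqrt(e) : 0.0;
      dnew(i) = std::max(d(i) - lambda, 0.0);
    }
    int r = 0;
    for (uword i = 0; i < nr; ++i) if (dnew(i) > 0) ++r;
    if (max_rank > 0 && r > max_rank) r = max_rank;
    d_keep = dnew;
    for (uword i = (uword)r; i < nr; ++i) d_keep(i) = 0.0;
    rank = r;

    double normZ2_new = 0.0;
    if (r == 0) {
      W.set_size(nr, 0);
      B.set_size(0, nc);
    } else {
      mat U(nr, r);
      for (int j = 0; j < r; ++j) U.col(j) = evec.col(nr - 1 - j);
      B = U.t() * M;        // r x nc
      W = U;
      for (int j = 0; j < r; ++j) {
        W.col(j) *= dnew(j) / std::max(d(j), 1e-300);
        normZ2_new += d_keep(j) * d_keep(j);
      }
    }

    double num;
    if (!have_old) {
      num = normZ2_new;
    } else {
      double cross = 0.0;
      if (rank > 0 && W_old.n_cols > 0) {
        mat C1 = W_old.t() * W;   // r_old x r
        mat C2 = B * B_old.t();   // r x r_old
        cross = accu(C1 % C2.t());
      }
      num = normZ2_new + normZ2_old - 2.0 * cross;
    }
    double den = std::max(have_old ? normZ2_old : 0.0, 1e-300);

    // refresh missing entries from the factored fit, one GEMM per run
    for (auto& rn : runs) {
      if (rank == 0) {
        for (uword c = rn.c0; c <= rn.c1; ++c)
          for (uword q = 0; q < rn.rows.n_elem; ++q) M(rn.rows(q), c) = 0.0;
      } else {
        mat Wr = W.rows(rn.rows);                       // m x r
        mat Zr = Wr * B.cols(rn.c0, rn.c1);             // m x len
        M.submat(rn.rows, rn.cols) = Zr;
      }
    }

    if (track_objective) {
      // M now equals X on observed cells and Z on missing cells, so the
      // observed-residual norm is accu((M - Z)^2)
      mat Z = (rank > 0) ? mat(W * B) : mat(nr, nc, fill::zeros);
      double obs_err = accu(square(M - Z));
      double nuc = 0.0;
      for (int j = 0; j < rank; ++j) nuc += d_keep(j);
      objective.push_back(0.5 * obs_err + lambda * nuc);
    }

    W_old = W; B_old = B; normZ2_old = normZ2_new; have_old = true;
    if (num / den < tol) { converged = true; break; }
  }

  mat Mout = wide ? M : mat(M.t());     // observed = X, missing = fit
  mat Zw = (rank > 0) ? mat(W * B) : mat(nr, nc, fill::zeros);
  mat Zfull = wide ? Zw : mat(Zw.t());

  return Rcpp::List::create(
    Rcpp::Named("completed") = Mout,
    Rcpp::Named("Z") = Zfull,
    Rcpp::Named("d") = d_keep,
    Rcpp::Named("rank") = rank,
    Rcpp::Named("objective") = objective,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
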