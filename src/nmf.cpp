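#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

//' Multiplicative-update NMF for squared Frobenius loss
//'
//' Core Lee--Seung update loop. Initial factors are supplied by the caller
//' (seeding and restarts are handled in R), so the routine itself is
//' deterministic. Iterations stop when the reconstruction R-squared has
//' improved by less than `tol` for `patience` consecutive iterations, or at
//' `max_iter`.
//'
//' @param V nonnegative matrix (muscles x time points)
//' @param W initial module matrix (muscles x rank), strictly positive
//' @param H initial primitive matrix (rank x time points), strictly positive
//' @param tol minimal R-squared improvement counted as progress
//' @param patience consecutive no-progress iterations tolerated before stopping
//' @param max_iter hard iteration cap
//' @return list with factors `W`, `H`, final `r2`, iteration count and the
//'   per-iteration Frobenius error trace `err_trace`
//' @keywords internal
// [[Rcpp::export(name = ".nmf_mu_cpp")]]
List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                double tol, int patience, int max_iter) {
  const double eps = 1e-12;
  const double vbar = arma::accu(V) / V.n_elem;
  const double sst = arma::accu(arma::square(V - vbar));

  arma::vec err_trace(max_iter, arma::fill::none);
  double r2_prev = -arma::datum::inf;
  int stall = 0;
  int it = 0;

  for (it = 0; it < max_iter; ++it) {
    // Lee-Seung multiplicative updates; nonnegativity is preserved because
    // every factor in the update ratios is nonnegative.
    H %= (W.t() * V) / (W.t() * W * H + eps);
    W %= (V * H.t()) / (W * H * H.t() + eps);

    const double err = arma::accu(arma::square(V - W * H));
    err_trace(it) = err;
    const double r2 = 1.0 - err / sst;

    if (r2 - r2_prev < tol) {
      if (++stall >= patience) { ++it; break; }
    } else {
      stall = 0;
    }
    r2_prev = r2;
  }

  const double err_final = arma::accu(arma::square(V - W * H));
  return List::create(
    _["W"] = W,
    _["H"] = H,
    _["r2"] = 1.0 - err_final / sst,
    _["iterations"] = it,
    _["err_trace"] = err_trace.head(it));
}
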