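// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// One training epoch of the 61->150->150->150->1 rectified-linear student:
// minibatch gradient descent on the mean squared error with Adam updates.
// Weight/bias matrices and Adam moment buffers are modified in place
// (zero-copy views onto the R matrices); returns the epoch's summed
// squared error. `ord` is the 1-based shuffled row order for this epoch,
// `step0` the Adam step count before the epoch.
//
// [[Rcpp::export(name = ".train_epoch_cpp")]]
double train_epoch_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::uvec& ord, List W, List B,
                       List mW, List vW, List mB, List vB,
                       int batch, double lr, double b1, double b2,
                       double eps, int step0) {
  const int n_layers = W.size();
  std::vector<arma::mat> w, mw, vw;
  std::vector<arma::vec> b, mb, vb;
  // reserve up front: vector reallocation would copy-construct the views,
  // detaching them from the R matrices they must update in place
  w.reserve(n_layers); mw.reserve(n_layers); vw.reserve(n_layers);
  b.reserve(n_layers); mb.reserve(n_layers); vb.reserve(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    NumericMatrix wi = W[l], mwi = mW[l], vwi = vW[l];
    NumericVector bi = B[l], mbi = mB[l], vbi = vB[l];
    w.emplace_back(wi.begin(), wi.nrow(), wi.ncol(), false, true);
    mw.emplace_back(mwi.begin(), mwi.nrow(), mwi.ncol(), false, true);
    vw.emplace_back(vwi.begin(), vwi.nrow(), vwi.ncol(), false, true);
    b.emplace_back(bi.begin(), bi.size(), false, true);
    mb.emplace_back(mbi.begin(), mbi.size(), false, true);
    vb.emplace_back(vbi.begin(), vbi.size(), false, true);
  }

  const int n = ord.n_elem;
  double sse = 0.0;
  int step = step0;
  std::vector<arma::mat> h(n_layers + 1);

  for (int start = 0; start < n; start += batch) {
    const int last = std::min(start + batch - 1, n - 1);
    const arma::uvec idx = ord.subvec(start, last) - 1;
    const int m = idx.n_elem;

    h[0] = X.rows(idx);
    for (int l = 0; l < n_layers; ++l) {
      arma::mat z = h[l] * w[l];
      z.each_row() += b[l].t();
      h[l + 1] = (l < n_layers - 1) ? arma::clamp(z, 0.0, arma::datum::inf)
                                    : z;
    }
    arma::vec err = h[n_layers].col(0) - y.elem(idx);
    if (!err.is_finite()) stop("non-finite loss; training aborted");
    sse += arma::dot(err, err);

    arma::mat delta = err * (2.0 / m);
    ++step;
    const double c1 = 1.0 - std::pow(b1, step);
    const double c2 = 1.0 - std::pow(b2, step);
    for (int l = n_layers - 1; l >= 0; --l) {
      arma::mat gw = h[l].t() * delta;
      arma::rowvec gb = arma::sum(delta, 0);
      if (l > 0) {
        delta = (delta * w[l].t()) %
          arma::conv_to<arma::mat>::from(h[l] > 0);
      }
      // compound in-place operators only: plain assignment to these
      // borrowed-memory views can reallocate and detach them from R
      mw[l] *= b1; mw[l] += (1.0 - b1) * gw;
      vw[l] *= b2; vw[l] += (1.0 - b2) * arma::square(gw);
      w[l] -= lr * (mw[l] / c1) / (arma::sqrt(vw[l] / c2) + eps);
      mb[l] *= b1; mb[l] += (1.0 - b1) * gb.t();
      vb[l] *= b2; vb[l] += (1.0 - b2) * arma::square(gb.t());
      b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
    }
  }
  return sse;
}

// Batched forward pass used for validation monitoring and bulk
// prediction: returns the network output for every row of X.
//
// [[Rcpp::export(name = ".mlp_forward_cpp")]]
NumericVector mlp_forward_cpp(const arma::mat& X, List W, List B) {
  const int n_layers = W.size();
  arma::mat h = X;
  for (int l = 0; l < n_layers; ++l) {
    NumericMatrix wi = W[l];
    NumericVector bi = B[l];
    const arma::mat w(wi.begin(), wi.nrow(), wi.ncol(), false, true);
    const arma::vec b(bi.begin(), bi.size(), false, true);
    h = h * w;
    h.each_row() += b.t();
    if (l < n_layers - 1) h = arma::clamp(h, 0.0, arma::datum::inf);
  }
  return wrap(h.col(0));
}
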