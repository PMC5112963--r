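// One-step contrastive divergence training loop for a single RBM layer.
// All randomness (per-epoch dropout mask, pattern shuffle, positive-phase
// Bernoulli hidden states) is drawn from R's global RNG stream, so results
// are reproducible with set.seed() from R.
//
// Per-epoch dropout is exploited for speed: the weight columns of the
// active hidden units are copied out once per epoch, trained, and written
// back, so every CD step scales with the number of active units.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline vec sigmoid(const vec &x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List cd1_train(const arma::mat &W0, const arma::vec &b0,
                     const arma::vec &c0, const arma::mat &data, int epochs,
                     double eps, double dropout_p, int minibatch,
                     bool sample_hidden, bool shuffle,
                     Rcpp::Nullable<Rcpp::NumericMatrix> mask) {
  mat W = W0;
  vec b = b0;
  vec c = c0;
  const int n = data.n_rows;
  const int nv = data.n_cols;
  const int nh = W.n_cols;
  if ((int)W.n_rows != nv)
    Rcpp::stop("data has %d columns but the layer expects %d", nv,
               (int)W.n_rows);
  const bool has_mask = mask.isNotNull();
  mat M;
  if (has_mask)
    M = Rcpp::as<mat>(mask.get());
  vec err(std::max(epochs, 0), fill::zeros);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i)
    order[i] = i;

  for (int e = 0; e < epochs; ++e) {
    uvec act;
    if (dropout_p > 0) {
      std::vector<arma::uword> keep;
      keep.reserve(nh);
      for (int j = 0; j < nh; ++j)
        if (R::unif_rand() >= dropout_p)
          keep.push_back(j);
      act = uvec(keep);
    } else {
      act = regspace<uvec>(0, nh - 1);
    }
    const int na = act.n_elem;
    mat Wa = W.cols(act);
    vec ba = b(act);
    mat Ma;
    if (has_mask)
      Ma = M.cols(act);

    if (shuffle) { // Fisher-Yates driven by R's RNG
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(R::unif_rand() * (i + 1));
        if (j > i)
          j = i;
        std::swap(order[i], order[j]);
      }
    }

    const bool accum = minibatch > 1;
    mat dW;
    vec db, dc;
    if (accum) {
      dW.zeros(nv, na);
      db.zeros(na);
      dc.zeros(nv);
    }
    int in_batch = 0;
    double etot = 0.0;

    for (int t = 0; t < n; ++t) {
      const vec v = data.row(order[t]).t();
      const vec h_pos = sigmoid(Wa.t() * v + ba);
      vec h_state(na);
      if (sample_hidden) {
        for (int j = 0; j < na; ++j)
          h_state[j] = (R::unif_rand() < h_pos[j]) ? 1.0 : 0.0;
      } else {
        h_state = h_pos;
      }
      const vec v_neg = sigmoid(Wa * h_state + c);
      const vec h_neg = sigmoid(Wa.t() * v_neg + ba);
      etot += mean(abs(v - v_neg));

      if (!accum && !has_mask) {
        // fast online path: both rank-1 updates fused into one pass over W
        const double *vp = v.memptr();
        const double *vn = v_neg.memptr();
        for (int j = 0; j < na; ++j) {
          const double hp = eps * h_pos[j];
          const double hn = eps * h_neg[j];
          double *wc = Wa.colptr(j);
          for (int i = 0; i < nv; ++i)
            wc[i] += hp * vp[i] - hn * vn[i];
        }
        ba += eps * (h_pos - h_neg);
        c += eps * (v - v_neg);
      } else {
        mat D = v * h_pos.t() - v_neg * h_neg.t();
        if (has_mask)
          D %= Ma;
        if (accum) {
          dW += D;
          db += h_pos - h_neg;
          dc += v - v_neg;
          if (++in_batch == minibatch || t == n - 1) {
            Wa += eps * dW;
            ba += eps * db;
            c += eps * dc;
            dW.zeros();
            db.zeros();
            dc.zeros();
            in_batch = 0;
          }
        } else {
          Wa += eps * D;
          ba += eps * (h_pos - h_neg);
          c += eps * (v - v_neg);
        }
      }
      if ((t & 1023) == 0)
        Rcpp::checkUserInterrupt();
    }
    err[e] = etot / n;
    W.cols(act) = Wa;
    b(act) = ba;
  }

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("b") = b, Rcpp::Named("c") = c,
      Rcpp::Named("error_log") = err);
}
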