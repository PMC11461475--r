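// Discrete-time AdLIF layer dynamics and their backward-through-time pass.
//
// State update per neuron (dimensionless, threshold = 1, rest = 0):
//   u_t = alpha * (u_{t-1} - s_{t-1}) + (1 - alpha) * (I_t - w_{t-1})
//   w_t = beta  * (w_{t-1} + b * s_{t-1}) + (1 - beta) * a * u_{t-1}
//   s_t = [u_t >= 1]
// with alpha = exp(-dt/tau_u), beta = exp(-dt/tau_w) and zero initial state.
// The layer stimulus is I_t = ff_t + s_{t-1} %*% Vt where ff_t collects the
// feedforward drive (precomputed in R as one large matrix product) and Vt is
// the transposed recurrent matrix with zero diagonal.
//
// Arrays are laid out as R arrays of dim c(B, T, N): element (b, t, n) lives
// at b + B*t + B*T*n, so a fixed-t slice is gathered with stride B*T across
// neurons.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat slice_bn(const double* x, int B, int T, int N, int t) {
  arma::mat out(B, N);
  for (int n = 0; n < N; ++n) {
    const double* col = x + (size_t)B * t + (size_t)B * T * n;
    std::copy(col, col + B, out.colptr(n));
  }
  return out;
}

static inline void store_bn(double* x, const arma::mat& m, int B, int T, int N,
                            int t) {
  for (int n = 0; n < N; ++n) {
    const double* col = m.colptr(n);
    std::copy(col, col + B, x + (size_t)B * t + (size_t)B * T * n);
  }
}

// [[Rcpp::export]]
List adlif_forward_cpp(NumericVector ff, NumericMatrix Vt_, NumericVector alpha_,
                       NumericVector beta_, NumericVector a_, NumericVector b_,
                       int B, int T, int N, bool recurrent) {
  arma::mat Vt(Vt_.begin(), Vt_.nrow(), Vt_.ncol(), false);
  arma::rowvec alpha(alpha_.begin(), N), beta(beta_.begin(), N);
  arma::rowvec aa(a_.begin(), N), bb(b_.begin(), N);

  NumericVector s_out((size_t)B * T * N), u_out((size_t)B * T * N),
      w_out((size_t)B * T * N);
  arma::mat u_prev(B, N, arma::fill::zeros), w_prev(B, N, arma::fill::zeros),
      s_prev(B, N, arma::fill::zeros);

  for (int t = 0; t < T; ++t) {
    arma::mat I = slice_bn(ff.begin(), B, T, N, t);
    if (recurrent) I += s_prev * Vt;
    arma::mat u = (u_prev - s_prev).eval();
    u.each_row() %= alpha;
    arma::mat drive = I - w_prev;
    drive.each_row() %= (1.0 - alpha);
    u += drive;
    arma::mat w = (w_prev + s_prev.each_row() % bb).eval();
    w.each_row() %= beta;
    arma::mat wa = u_prev.each_row() % ((1.0 - beta) % aa);
    w += wa;
    arma::mat s = arma::conv_to<arma::mat>::from(u >= 1.0);
    store_bn(u_out.begin(), u, B, T, N, t);
    store_bn(w_out.begin(), w, B, T, N, t);
    store_bn(s_out.begin(), s, B, T, N, t);
    u_prev = u;
    w_prev = w;
    s_prev = s;
  }
  IntegerVector dims = IntegerVector::create(B, T, N);
  s_out.attr("dim") = dims;
  u_out.attr("dim") = dims;
  w_out.attr("dim") = dims;
  return List::create(_["s"] = s_out, _["u"] = u_out, _["w"] = w_out);
}

// Backward-through-time with the boxcar surrogate ds/du = 0.5 * [|u-1| <= 0.5].
// gs_ext carries the downstream gradient on the emitted spikes (next layer,
// readout head, rate regularizer). Returns the gradient on the feedforward
// drive ff (from which W gradients and the previous layer's spike gradients
// are obtained in R by one large matrix product each), the recurrent-weight
// gradient gVt, and per-neuron gradients on alpha, beta, a, b.
// [[Rcpp::export]]
List adlif_backward_cpp(NumericVector gs_ext, NumericVector s, NumericVector u,
                        NumericVector w, NumericMatrix Vt_,
                        NumericVector alpha_, NumericVector beta_,
                        NumericVector a_, NumericVector b_, int B, int T, int N,
                        bool recurrent) {
  arma::mat Vt(Vt_.begin(), Vt_.nrow(), Vt_.ncol(), false);
  arma::rowvec alpha(alpha_.begin(), N), beta(beta_.begin(), N);
  arma::rowvec aa(a_.begin(), N), bb(b_.begin(), N);

  NumericVector g_ff((size_t)B * T * N);
  arma::mat gVt(N, N, arma::fill::zeros);
  arma::rowvec g_alpha(N, arma::fill::zeros), g_beta(N, arma::fill::zeros),
      g_a(N, arma::fill::zeros), g_b(N, arma::fill::zeros);

  arma::mat gu_next(B, N, arma::fill::zeros), gw_next(B, N, arma::fill::zeros);
  arma::mat gI_next(B, N, arma::fill::zeros);  // dL/dI_{t+1}
  arma::mat zeros(B, N, arma::fill::zeros);

  for (int t = T - 1; t >= 0; --t) {
    arma::mat u_t = slice_bn(u.begin(), B, T, N, t);
    arma::mat u_tm1 = (t > 0) ? slice_bn(u.begin(), B, T, N, t - 1) : zeros;
    arma::mat w_tm1 = (t > 0) ? slice_bn(w.begin(), B, T, N, t - 1) : zeros;
    arma::mat s_tm1 = (t > 0) ? slice_bn(s.begin(), B, T, N, t - 1) : zeros;

    // total gradient on s_t: external + s_t -> I_{t+1} (recurrence)
    //                       + s_t -> u_{t+1} (reset) + s_t -> w_{t+1} (b jump)
    arma::mat gs = slice_bn(gs_ext.begin(), B, T, N, t);
    if (recurrent) gs += gI_next * Vt.t();
    gs -= gu_next.each_row() % alpha;
    gs += gw_next.each_row() % (beta % bb);

    // surrogate derivative of the threshold
    arma::mat sur = arma::conv_to<arma::mat>::from(arma::abs(u_t - 1.0) <= 0.5);
    arma::mat gu = gs % sur * 0.5;
    gu += gu_next.each_row() % alpha;
    gu += gw_next.each_row() % ((1.0 - beta) % aa);
    arma::mat gw = gw_next.each_row() % beta;
    gw -= gu_next.each_row() % (1.0 - alpha);

    arma::mat gI = gu.each_row() % (1.0 - alpha);
    store_bn(g_ff.begin(), gI, B, T, N, t);
    if (recurrent && t > 0) gVt += s_tm1.t() * gI;

    // d u_t/d alpha = (u_{t-1}-s_{t-1}) - (I_t - w_{t-1}),
    // with I_t - w_{t-1} recovered from the forward pass.
    arma::mat du_dalpha = u_tm1 - s_tm1;
    arma::mat drive = u_t - du_dalpha.each_row() % alpha;  // (1-alpha)(I-w)
    drive.each_row() /= (1.0 - alpha);
    du_dalpha -= drive;
    g_alpha += arma::sum(gu % du_dalpha, 0);
    arma::mat dw_dbeta = w_tm1 + s_tm1.each_row() % bb;
    dw_dbeta -= u_tm1.each_row() % aa;
    g_beta += arma::sum(gw % dw_dbeta, 0);
    g_a += arma::sum(gw % u_tm1, 0) % (1.0 - beta);
    g_b += arma::sum(gw % s_tm1, 0) % beta;

    gu_next = gu;
    gw_next = gw;
    gI_next = gI;
  }
  g_ff.attr("dim") = IntegerVector::create(B, T, N);
  return List::create(
      _["g_ff"] = g_ff, _["gVt"] = wrap(gVt), _["g_alpha"] = wrap(g_alpha),
      _["g_beta"] = wrap(g_beta), _["g_a"] = wrap(g_a), _["g_b"] = wrap(g_b));
}
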