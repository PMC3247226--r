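#include <Rcpp.h>
using namespace Rcpp;

// Online back-propagation with momentum for a 1 -> H -> K tanh perceptron
// without bias units. All stochastic choices (initial weights, per-epoch
// presentation orders) are made on the R side, so this routine is purely
// deterministic given its arguments.
//
// x:       M input scalars (one per training pattern)
// targets: M x K matrix of target outputs
// w_in:    H input->hidden weights
// w_out:   H x K hidden->output weights
// order:   epochs x M matrix of 1-based presentation orders
// eta:     learning rate; alpha: momentum
//
// The per-pattern error is E = 1/2 * sum_k (y_k - t_k)^2 and the update is
// dw(t) = -eta * dE/dw + alpha * dw(t-1).
// [[Rcpp::export]]
List bp_train(NumericVector x, NumericMatrix targets,
              NumericVector w_in, NumericMatrix w_out,
              IntegerMatrix order, double eta, double alpha) {
  const int M = x.size();
  const int H = w_in.size();
  const int K = targets.ncol();
  const int epochs = order.nrow();
  if (targets.nrow() != M)
    stop("targets must have one row per input pattern");
  if (w_out.nrow() != H || w_out.ncol() != K)
    stop("w_out dimensions do not match hidden size and target width");
  if (order.ncol() != M)
    stop("order must have one column per pattern");

  NumericVector wi = clone(w_in);
  NumericMatrix wo = clone(w_out);
  NumericVector dwi(H);          // momentum buffers
  NumericMatrix dwo(H, K);
  NumericVector epoch_error(epochs);

  std::vector<double> h(H), delta_out(K);

  for (int ep = 0; ep < epochs; ++ep) {
    double err_sum = 0.0;
    for (int pos = 0; pos < M; ++pos) {
      const int i = order(ep, pos) - 1;
      const double xi = x[i];

      for (int j = 0; j < H; ++j) h[j] = std::tanh(wi[j] * xi);

      double E = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < H; ++j) a += wo(j, k) * h[j];
        const double y = std::tanh(a);
        const double e = y - targets(i, k);
        E += 0.5 * e * e;
        delta_out[k] = e * (1.0 - y * y);
      }
      err_sum += E;

      // gradients w.r.t. pre-update weights, then simultaneous update
      for (int j = 0; j < H; ++j) {
        double back = 0.0;
        for (int k = 0; k < K; ++k) {
          const double g = delta_out[k] * h[j];
          dwo(j, k) = -eta * g + alpha * dwo(j, k);
          back += wo(j, k) * delta_out[k];
        }
        const double g_in = back * (1.0 - h[j] * h[j]) * xi;
        dwi[j] = -eta * g_in + alpha * dwi[j];
      }
      for (int j = 0; j < H; ++j) {
        wi[j] += dwi[j];
        for (int k = 0; k < K; ++k) wo(j, k) += dwo(j, k);
      }
    }
    epoch_error[ep] = err_sum / M;
    if (!R_finite(epoch_error[ep]))
      stop("training diverged (non-finite weights); lower the learning rate eta");
  }
  for (int j = 0; j < H; ++j) {
    if (!R_finite(wi[j]))
      stop("training diverged (non-finite weights); lower the learning rate eta");
    for (int k = 0; k < K; ++k)
      if (!R_finite(wo(j, k)))
        stop("training diverged (non-finite weights); lower the learning rate eta");
  }

  return List::create(_["w_in"] = wi, _["w_out"] = wo,
                      _["prev_in"] = dwi, _["prev_out"] = dwo,
                      _["epoch_error"] = epoch_error);
}
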