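# Independent oracles used across the suite. Everything here is deliberately
# naive (double loops, exhaustive enumeration) and must stay independent of
# the package's own code paths.

# matrix-free double-loop forward pass of the 1 -> H -> K tanh network
ref_forward <- function(w_in, w_out, x) {
  h <- length(w_in)
  k <- ncol(w_out)
  y <- numeric(k)
  for (j in seq_len(k)) {
    a <- 0
    for (i in seq_len(h)) a <- a + w_out[i, j] * tanh(w_in[i] * x)
    y[j] <- tanh(a)
  }
  y
}

# per-pattern error E = 1/2 sum_k (y_k - t_k)^2 of the same network
ref_pattern_error <- function(w_in, w_out, x, target) {
  y <- ref_forward(w_in, w_out, x)
  0.5 * sum((y - target)^2)
}

# central finite differences of E w.r.t. every weight
fd_gradient <- function(w_in, w_out, x, target, h = 1e-6) {
  g_in <- numeric(length(w_in))
  for (i in seq_along(w_in)) {
    up <- w_in; up[i] <- up[i] + h
    dn <- w_in; dn[i] <- dn[i] - h
    g_in[i] <- (ref_pattern_error(up, w_out, x, target) -
                ref_pattern_error(dn, w_out, x, target)) / (2 * h)
  }
  g_out <- matrix(0, nrow(w_out), ncol(w_out))
  for (i in seq_len(nrow(w_out))) {
    for (j in seq_len(ncol(w_out))) {
      up <- w_out; up[i, j] <- up[i, j] + h
      dn <- w_out; dn[i, j] <- dn[i, j] - h
      g_out[i, j] <- (ref_pattern_error(w_in, up, x, target) -
                      ref_pattern_error(w_in, dn, x, target)) / (2 * h)
    }
  }
  list(g_in = g_in, g_out = g_out)
}

# gradient actually used by the training engine, extracted from a single
# momentum-free step: w1 = w0 - eta * grad  =>  grad = (w0 - w1) / eta
impl_gradient <- function(w_in, w_out, x, target, eta = 1) {
  fit <- regnann:::bp_train(x, matrix(target, nrow = 1),
                            w_in, w_out,
                            matrix(1L, 1, 1), eta, 0)
  list(g_in = (w_in - fit$w_in) / eta,
       g_out = (w_out - fit$w_out) / eta)
}

# random symmetric binary adjacency matrix with zero diagonal
rand_adjacency <- function(n, p = 0.3) {
  m <- matrix(0L, n, n)
  m[upper.tri(m)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  m + t(m)
}

# brute-force confusion counts by explicit pair enumeration
ref_confusion <- function(true_adj, pred_adj) {
  n <- ncol(true_adj)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      t <- true_adj[i, j]; p <- pred_adj[i, j]
      if (t == 1 && p == 1) tp <- tp + 1L
      else if (t == 0 && p == 1) fp <- fp + 1L
      else if (t == 0 && p == 0) tn <- tn + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

ref_mcc <- function(tp, fp, tn, fn) {
  f <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(f == 0)) return(0)
  (tp * tn - fp * fn) / sqrt(prod(as.numeric(f)))
}

# random symmetric score matrix, independent of any truth
rand_scores <- function(n) {
  s <- matrix(stats::runif(n * n, -1, 1), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 0
  class(s) <- c("correlation_matrix", "matrix", "array")
  s
}

# scorer stubs for the protocol plumbing: return the truth / pure noise
truth_scorer <- function(expr, truth, params) unclass(truth) * 1.0
null_scorer <- function(expr, truth, params) {
  # seed from the data content so distinct inputs (e.g. the two halves of a
  # split) get independent score matrices
  set.seed((params$seed + round(sum(abs(expr)) * 1e4)) %% 2147483647L)
  rand_scores(ncol(truth))
}
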