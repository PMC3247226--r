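#' Learning parameters for the per-gene regressors
#'
#' Controls the online back-propagation training of each gene's multilayer
#' perceptron.
#'
#' @param learning_rate gradient step size eta (>= 0; 0 disables learning, so
#'   weights stay at their initialization).
#' @param momentum fraction alpha of the previous update added to the current
#'   one, in `[0, 1)`.
#' @param epochs number of passes over the training patterns (>= 1).
#' @param hidden optional override of the hidden layer size; by default
#'   `ceiling(sqrt(n_genes - 1))` (the square root of the number of inputs
#'   times the number of outputs).
#' @param init_scale half-width of the uniform weight initialization (> 0).
#' @param seed base seed; per-gene seeds are derived as `seed + target_gene`,
#'   and majority-vote runs as `seed + run * n_genes`, so ensembles are
#'   reproducible yet decorrelated.
#' @return an object of class `"learning_params"`.
#' @export
learning_params <- function(learning_rate = 0.01, momentum = 0.8, epochs = 200,
                            hidden = NULL, init_scale = 0.1, seed = 1) {
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (!is.null(hidden) && hidden < 1) stop("hidden must be >= 1", call. = FALSE)
  if (init_scale <= 0) stop("init_scale must be > 0", call. = FALSE)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), hidden = hidden,
                 init_scale = init_scale, seed = as.integer(seed)),
            class = "learning_params")
}

hidden_size <- function(n_genes, params) {
  if (!is.null(params$hidden)) as.integer(params$hidden)
  else as.integer(ceiling(sqrt(n_genes - 1)))
}

check_rescaled <- function(expr) {
  vals <- unclass(expr)
  if (ncol(vals) < 2) stop("need at least two genes", call. = FALSE)
  if (any(!is.finite(vals)) || max(abs(vals)) > 1 + 1e-8)
    stop(paste("expression values must lie in [-1, 1]; apply rescale_linear()",
               "before inference (tanh outputs cannot match unbounded targets)"),
         call. = FALSE)
  invisible(vals)
}

#' Build training patterns for one gene's regressor
#'
#' Each expression sample yields one pattern: the input is the target gene's
#' expression value, the output pattern is the same row with the target gene's
#' column removed (order of the remaining genes preserved).
#'
#' @param expr expression matrix, linearly rescaled to \[-1, 1\].
#' @param target_gene column index (1-based) or gene name.
#' @return a list with `input` (length-M vector), `targets` (M x (N-1) matrix)
#'   and `output_genes` (labels of the N-1 outputs).
#' @export
build_patterns <- function(expr, target_gene) {
  vals <- check_rescaled(expr)
  if (is.character(target_gene)) target_gene <- match(target_gene, colnames(vals))
  if (is.na(target_gene) || target_gene < 1 || target_gene > ncol(vals))
    stop("target_gene is not a column of the expression matrix", call. = FALSE)
  list(input = vals[, target_gene],
       targets = vals[, -target_gene, drop = FALSE],
       output_genes = colnames(vals)[-target_gene])
}

#' Forward pass of a gene regressor
#'
#' Computes `y_j = tanh( sum_h w_out[h, j] * tanh(w_in[h] * x) )`, the inferred
#' normalized expression of every other gene given input `x` for the target
#' gene. No bias units: an input of zero yields outputs of zero.
#'
#' @param reg a [train_gene()] regressor.
#' @param x input scalar.
#' @return numeric vector of length N - 1 in (-1, 1).
#' @export
forward_regressor <- function(reg, x) {
  h <- tanh(reg$w_in * x)
  y <- tanh(drop(crossprod(reg$w_out, h)))
  names(y) <- reg$output_genes
  y
}

#' Train one gene's multilayer perceptron regressor
#'
#' Builds the gene's training patterns and fits a 1 -> H -> (N-1) tanh network
#' by online back-propagation with momentum: per-pattern update
#' `dw(t) = -eta * grad(E) + alpha * dw(t-1)` with error `E` equal to half the
#' sum of squared output deviations. Weights are initialized uniformly on
#' `[-init_scale, init_scale]` from `params$seed + target_gene`, and patterns
#' are presented in a freshly shuffled order each epoch (also seeded).
#'
#' @inheritParams build_patterns
#' @param params a [learning_params()] object.
#' @return an object of class `"gene_regressor"` with the trained weights,
#'   momentum buffers and the mean per-pattern training error per epoch.
#' @export
train_gene <- function(expr, target_gene, params = learning_params()) {
  pat <- build_patterns(expr, target_gene)
  if (is.character(target_gene)) target_gene <- match(target_gene, colnames(expr))
  m <- length(pat$input)
  k <- ncol(pat$targets)
  h <- hidden_size(k + 1L, params)

  set.seed(params$seed + as.integer(target_gene))
  w_in <- stats::runif(h, -params$init_scale, params$init_scale)
  w_out <- matrix(stats::runif(h * k, -params$init_scale, params$init_scale), h, k)
  order <- do.call(rbind, lapply(seq_len(params$epochs),
                                 function(e) sample.int(m)))

  fit <- bp_train(pat$input, pat$targets, w_in, w_out, order,
                  params$learning_rate, params$momentum)
  structure(list(target_gene = as.integer(target_gene),
                 output_genes = pat$output_genes,
                 w_in = fit$w_in,
                 w_out = fit$w_out,
                 prev_in = fit$prev_in,
                 prev_out = fit$prev_out,
                 epoch_error = fit$epoch_error,
                 params = params),
            class = "gene_regressor")
}

#' @export
print.gene_regressor <- function(x, ...) {
  cat(sprintf("gene regressor: target %d, %d hidden units, %d outputs; final training error %.4g\n",
              x$target_gene, length(x$w_in), ncol(x$w_out),
              x$epoch_error[length(x$epoch_error)]))
  invisible(x)
}

#' Probe a trained regressor at maximal expression
#'
#' Feeds the maximal normalized input (1) to the regressor and returns its
#' outputs, read as interaction estimates for every other gene: values near +1
#' indicate correlation, near -1 anti-correlation, near 0 no correlation. Pure
#' function of the trained weights.
#'
#' @param reg a trained [train_gene()] regressor.
#' @return numeric vector of length N - 1 in (-1, 1).
#' @export
probe <- function(reg) {
  forward_regressor(reg, 1.0)
}

#' Infer the full correlation matrix of a network
#'
#' Trains one regressor per gene (each seeded independently, so results do not
#' depend on the order of execution) and joins the probed neighbourhoods into
#' an N x N correlation matrix. Row g holds gene g's probed interaction
#' estimates with 0 at position g: self-regulation is excluded by
#' construction.
#'
#' @inheritParams train_gene
#' @return an N x N matrix of class `"correlation_matrix"` with entries in
#'   (-1, 1) and a zero diagonal.
#' @export
infer_network <- function(expr, params = learning_params()) {
  vals <- check_rescaled(expr)
  n <- ncol(vals)
  genes <- colnames(vals)
  corr <- matrix(0, n, n, dimnames = list(genes, genes))
  for (g in seq_len(n)) {
    corr[g, -g] <- probe(train_gene(expr, g, params))
  }
  class(corr) <- c("correlation_matrix", "matrix", "array")
  corr
}

pair_strength <- function(corr, combine = c("max", "mean", "signed_max"),
                          absolute = TRUE) {
  combine <- match.arg(combine)
  corr <- unclass(corr)
  a <- if (absolute) abs(corr) else corr
  s <- switch(combine,
    max = pmax(a, t(a)),
    mean = (a + t(a)) / 2,
    signed_max = {
      pick <- abs(corr) >= abs(t(corr))
      ifelse(pick, corr, t(corr))
    })
  diag(s) <- 0
  s
}

#' Binarize a correlation matrix into a network
#'
#' The undirected strength of a pair is the larger magnitude of its two
#' directed scores, `max(|c_ij|, |c_ji|)` by default; a link is present when
#' the strength strictly exceeds the threshold. Anti-correlation counts as
#' interaction unless `absolute = FALSE`.
#'
#' @param corr correlation matrix from [infer_network()].
#' @param threshold binarization threshold in `[0, 1]` (strict inequality).
#' @param combine how the two directed scores are merged: `"max"` (default),
#'   `"mean"` or `"signed_max"`.
#' @param absolute take absolute values before combining (default `TRUE`).
#' @return an [as_adjacency()] matrix.
#' @export
binarize <- function(corr, threshold, combine = c("max", "mean", "signed_max"),
                     absolute = TRUE) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  s <- pair_strength(corr, combine, absolute)
  adj <- (s > threshold) * 1L
  diag(adj) <- 0L
  as_adjacency(adj, labels = colnames(corr) %||% paste0("gene", seq_len(ncol(s))))
}

#' Majority-vote network inference
#'
#' Smooths out local minima of the stochastic training: the whole inference is
#' repeated `n_runs` times with derived seeds (`seed + run * n_genes`), each
#' run is binarized, and links are kept when their appearance frequency
#' strictly exceeds `vote_fraction`.
#'
#' @inheritParams train_gene
#' @param n_runs number of independent inference runs (>= 1).
#' @param threshold binarization threshold applied to each run.
#' @param vote_fraction minimum appearance frequency (strict), in `[0, 1]`.
#' @inheritParams binarize
#' @return an [as_adjacency()] matrix.
#' @export
majority_vote <- function(expr, params = learning_params(), n_runs = 10,
                          threshold = 0.5, vote_fraction = 0.5,
                          combine = "max", absolute = TRUE) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  if (vote_fraction < 0 || vote_fraction > 1)
    stop("vote_fraction must lie in [0, 1]", call. = FALSE)
  n <- ncol(expr)
  acc <- matrix(0, n, n)
  for (run in seq_len(n_runs)) {
    run_params <- params
    # run 1 keeps the base seed, so a single vote run equals plain inference
    run_params$seed <- params$seed + (run - 1L) * n
    acc <- acc + unclass(binarize(infer_network(expr, run_params), threshold,
                                  combine, absolute))
  }
  adj <- (acc / n_runs > vote_fraction) * 1L
  as_adjacency(adj, labels = colnames(expr) %||% paste0("gene", seq_len(n)))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("inferred correlation matrix: %d genes\n", ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Write or read a correlation matrix as labeled TSV
#' @param corr correlation matrix.
#' @param path file path.
#' @return `read_correlation` returns a `"correlation_matrix"`;
#'   `write_correlation` returns `path` invisibly.
#' @export
write_correlation <- function(corr, path) {
  utils::write.table(unclass(corr), path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  mat <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (nrow(mat) != ncol(mat)) stop("correlation file is not square", call. = FALSE)
  class(mat) <- c("correlation_matrix", "matrix", "array")
  mat
}

#' @export
glance.gene_regressor <- function(x, ...) {
  tibble::tibble(target_gene = x$target_gene,
                 hidden = length(x$w_in),
                 outputs = ncol(x$w_out),
                 epochs = length(x$epoch_error),
                 final_error = x$epoch_error[length(x$epoch_error)])
}
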