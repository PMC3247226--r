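#' Expression matrices
#'
#' An expression matrix holds M samples (rows) by N genes (columns) of real
#' expression values, plus a record of the normalization applied: one of
#' `"raw"`, `"linear_rescaled"`, `"statistical"` or `"discretized"`.
#'
#' @param values numeric M x N matrix (rows = samples, columns = genes).
#' @param normalization normalization state of the values.
#' @return a matrix of class `"expression_matrix"` with a `normalization`
#'   attribute.
#' @export
as_expression <- function(values,
                          normalization = c("raw", "linear_rescaled",
                                            "statistical", "discretized")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric", call. = FALSE)
  if (is.null(colnames(values))) colnames(values) <- paste0("gene", seq_len(ncol(values)))
  attr(values, "normalization") <- normalization
  class(values) <- c("expression_matrix", "matrix", "array")
  values
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  norm <- attr(x, "normalization")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "normalization") <- norm
    class(out) <- c("expression_matrix", "matrix", "array")
  }
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d samples x %d genes (normalization: %s)\n",
              nrow(x), ncol(x), attr(x, "normalization")))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more samples\n", nrow(x) - 6L))
  invisible(x)
}

#' Normalization state of an expression matrix
#' @param expr an expression matrix.
#' @return the normalization label.
#' @export
normalization <- function(expr) attr(expr, "normalization") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize linearly correlated expression from a topology
#'
#' Simple linear correlation (SLC) synthesis: a seed matrix S (M x N, entries
#' uniform on \[-1, 1\]) is propagated once through the adjacency matrix,
#' `E = S + S %*% adjM`, so each gene's profile is its own seed plus the seeds
#' of its neighbours. Linked columns become linearly correlated; an empty
#' topology returns the seeds unchanged.
#'
#' @param adj ground-truth adjacency matrix.
#' @param n_samples number of expression profiles M (>= 1).
#' @param seed optional integer seed; same arguments give bit-identical output.
#' @return a raw [as_expression()] matrix with the topology's gene labels.
#' @export
generate_slc <- function(adj, n_samples, seed = NULL) {
  adj <- as_adjacency(adj)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(adj)
  s <- matrix(stats::runif(n_samples * n, -1, 1), n_samples, n)
  e <- s + s %*% unclass(adj)
  colnames(e) <- colnames(adj)
  as_expression(e, "raw")
}

#' Specify a four-gene toy regulatory motif
#'
#' Four small motifs over genes A, B, C, D illustrate direct, cooperative,
#' multiple and indirect regulation:
#' * `single`: A regulates B. A is inactive (0) with probability `1 - p_active`,
#'   otherwise uniform on (0, 1\]; when active, B follows A plus noise,
#'   otherwise B is pure noise. C and D are pure noise.
#' * `cooperative`: A and B cooperatively regulate C: C equals `s_A + s_B`
#'   (plus noise) when `|s_A + s_B| > theta`, else noise. D is isolated.
#' * `multiple`: A regulates both B and C through the same threshold gate on
#'   `s_A`. D is isolated.
#' * `indirect`: a chain A -> B -> C; B is gated on `s_A`, C is gated on the
#'   realized B profile. D is isolated.
#'
#' The activation threshold, noise amplitude and activation probability are
#' tunable; the motif structure is fixed.
#'
#' @param motif one of `"single"`, `"cooperative"`, `"multiple"`, `"indirect"`.
#' @param n_samples number of expression profiles (>= 1).
#' @param theta activation threshold for the gated motifs.
#' @param noise noise amplitude; regulated values get additive noise uniform on
#'   `[-noise, noise]` (>= 0).
#' @param p_active probability that the regulator is active (single motif only).
#' @param seed optional integer seed.
#' @return an object of class `"toy_spec"`.
#' @export
toy_spec <- function(motif = c("single", "cooperative", "multiple", "indirect"),
                     n_samples = 100, theta = 0.5, noise = 0.1,
                     p_active = 0.5, seed = NULL) {
  motif <- match.arg(motif)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (noise < 0) stop("noise amplitude must be >= 0", call. = FALSE)
  if (p_active < 0 || p_active > 1) stop("p_active must lie in [0, 1]", call. = FALSE)
  structure(list(motif = motif, n_samples = n_samples, theta = theta,
                 noise = noise, p_active = p_active, seed = seed),
            class = "toy_spec")
}

toy_truth <- function(motif) {
  labels <- c("A", "B", "C", "D")
  links <- switch(motif,
    single      = list(c("A", "B")),
    cooperative = list(c("A", "C"), c("B", "C")),
    multiple    = list(c("A", "B"), c("A", "C")),
    indirect    = list(c("A", "B"), c("B", "C")),
    stop(sprintf("unknown motif '%s'", motif), call. = FALSE))
  mat <- matrix(0L, 4, 4, dimnames = list(labels, labels))
  for (lk in links) {
    mat[lk[1], lk[2]] <- 1L
    mat[lk[2], lk[1]] <- 1L
  }
  as_adjacency(mat, labels)
}

#' Generate expression data for a toy motif
#'
#' Draws expression profiles for the motif in `spec` and returns them linearly
#' rescaled to \[-1, 1\] together with the motif's ground-truth adjacency
#' matrix.
#'
#' @param spec a [toy_spec()].
#' @return a list with elements `expr` (rescaled expression matrix) and
#'   `truth` (adjacency matrix).
#' @export
generate_toy <- function(spec) {
  if (!inherits(spec, "toy_spec")) spec <- do.call(toy_spec, as.list(spec))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  m <- spec$n_samples
  eps <- function() stats::runif(m, -spec$noise, spec$noise)
  gate <- function(driver, gated_on) {
    # driver value + noise where the gate opens, fresh uniform noise elsewhere
    out <- stats::runif(m, -1, 1)
    out[gated_on] <- driver[gated_on] + eps()[gated_on]
    out
  }
  vals <- switch(spec$motif,
    single = {
      active <- stats::runif(m) < spec$p_active
      a <- ifelse(active, stats::runif(m), 0)
      b <- stats::runif(m)                  # pure noise when A inactive
      b[active] <- a[active] + eps()[active]
      cbind(A = a, B = b, C = stats::runif(m), D = stats::runif(m))
    },
    cooperative = {
      s <- matrix(stats::runif(4 * m, -1, 1), m, 4)
      drive <- s[, 1] + s[, 2]
      cbind(A = s[, 1], B = s[, 2],
            C = gate(drive, abs(drive) > spec$theta), D = s[, 4])
    },
    multiple = {
      s <- matrix(stats::runif(4 * m, -1, 1), m, 4)
      on <- abs(s[, 1]) > spec$theta
      cbind(A = s[, 1], B = gate(s[, 1], on), C = gate(s[, 1], on), D = s[, 4])
    },
    indirect = {
      s <- matrix(stats::runif(4 * m, -1, 1), m, 4)
      b <- gate(s[, 1], abs(s[, 1]) > spec$theta)
      cbind(A = s[, 1], B = b, C = gate(b, abs(b) > spec$theta), D = s[, 4])
    })
  expr <- rescale_linear(as_expression(vals, "raw"))
  list(expr = expr, truth = toy_truth(spec$motif))
}

#' Linearly rescale each gene to \[-1, 1\]
#'
#' Applies the per-column affine map sending the column minimum to -1 and the
#' maximum to +1. Constant columns carry no signal and map to all zeros (the
#' midpoint). Idempotent.
#'
#' @param expr an expression matrix (or plain numeric matrix).
#' @return an expression matrix with normalization `"linear_rescaled"`.
#' @export
rescale_linear <- function(expr) {
  expr <- if (inherits(expr, "expression_matrix")) expr else as_expression(expr)
  vals <- unclass(expr)
  lo <- apply(vals, 2, min)
  hi <- apply(vals, 2, max)
  rng <- hi - lo
  out <- vals
  for (j in seq_len(ncol(vals))) {
    out[, j] <- if (rng[j] == 0) 0 else 2 * (vals[, j] - lo[j]) / rng[j] - 1
  }
  as_expression(out, "linear_rescaled")
}

#' Statistically normalize each gene (z-score)
#'
#' Centres each column to mean 0 and scales to standard deviation 1, using the
#' population (1/M) standard deviation. Constant columns map to zeros with a
#' warning.
#'
#' @inheritParams rescale_linear
#' @return an expression matrix with normalization `"statistical"`.
#' @export
normalize_statistical <- function(expr) {
  expr <- if (inherits(expr, "expression_matrix")) expr else as_expression(expr)
  vals <- unclass(expr)
  mu <- colMeans(vals)
  centred <- sweep(vals, 2, mu)
  sd_pop <- sqrt(colMeans(centred^2))
  if (any(sd_pop == 0)) {
    warning("constant column(s) mapped to zeros during statistical normalization",
            call. = FALSE)
  }
  out <- centred
  for (j in seq_len(ncol(vals))) {
    out[, j] <- if (sd_pop[j] == 0) 0 else centred[, j] / sd_pop[j]
  }
  as_expression(out, "statistical")
}

#' Discretize expression as signs of successive differences
#'
#' Replaces each gene's profile by the sign of the difference between
#' consecutive expression values, so row t of the output is
#' `sign(E[t + 1, ] - E[t, ])` with values in `{-1, 0, +1}`. The output has one
#' row fewer than the input.
#'
#' @inheritParams rescale_linear
#' @return an expression matrix with normalization `"discretized"`.
#' @export
discretize_signs <- function(expr) {
  expr <- if (inherits(expr, "expression_matrix")) expr else as_expression(expr)
  vals <- unclass(expr)
  if (nrow(vals) < 2)
    stop("discretization needs at least two samples", call. = FALSE)
  out <- sign(diff(vals))
  colnames(out) <- colnames(vals)
  as_expression(out, "discretized")
}

#' Read and write expression matrices
#'
#' Tab-separated files with a header row of gene labels, one row per sample,
#' and a leading comment line `# normalization=<state>` recording the
#' normalization state.
#'
#' @param expr expression matrix to write.
#' @param path file path.
#' @return `read_expression` returns an expression matrix; `write_expression`
#'   returns `path` invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- if (inherits(expr, "expression_matrix")) expr else as_expression(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalization=%s", normalization(expr)), con)
  utils::write.table(unclass(expr), con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1)
  norm <- "raw"
  if (grepl("^# normalization=", first))
    norm <- sub("^# normalization=", "", first)
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  as_expression(as.matrix(tab), norm)
}
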