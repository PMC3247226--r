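#' Construct and validate an adjacency matrix
#'
#' Ground-truth and predicted network topologies are undirected and unweighted,
#' represented as symmetric binary matrices with a zero diagonal (no
#' self-regulation). `as_adjacency()` validates an existing matrix and attaches
#' node labels; generators below return objects already in this form.
#'
#' @param mat square numeric matrix containing only 0 and 1.
#' @param labels optional character vector of node labels; defaults to existing
#'   dimnames or `gene1..geneN`.
#' @return the validated matrix, with class `"adjacency_matrix"` and labels as
#'   dimnames.
#' @export
as_adjacency <- function(mat, labels = NULL) {
  mat <- as.matrix(mat)
  validate_adjacency(mat)
  if (is.null(labels)) {
    labels <- if (!is.null(colnames(mat))) colnames(mat) else paste0("gene", seq_len(ncol(mat)))
  }
  if (length(labels) != ncol(mat)) stop("labels must have one entry per node", call. = FALSE)
  dimnames(mat) <- list(labels, labels)
  class(mat) <- c("adjacency_matrix", "matrix", "array")
  mat
}

validate_adjacency <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("adjacency matrix must be square", call. = FALSE)
  bad <- which(!(mat == 0 | mat == 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("adjacency entries must be 0 or 1; offending cell (%d, %d) = %s",
                 bad[1, 1], bad[1, 2], format(mat[bad[1, , drop = FALSE]])), call. = FALSE)
  asym <- which(mat != t(mat), arr.ind = TRUE)
  if (nrow(asym) > 0)
    stop(sprintf("adjacency matrix must be symmetric; cell (%d, %d) != cell (%d, %d)",
                 asym[1, 1], asym[1, 2], asym[1, 2], asym[1, 1]), call. = FALSE)
  if (any(diag(mat) != 0))
    stop(sprintf("adjacency diagonal must be zero; offending cell (%d, %d)",
                 which(diag(mat) != 0)[1], which(diag(mat) != 0)[1]), call. = FALSE)
  invisible(mat)
}

#' Sample a Barabasi-Albert preferential-attachment topology
#'
#' Grows a graph one node at a time; each new node attaches `edges_per_step`
#' links to existing nodes with probability proportional to
#' `(degree + 1)^power`, so degree-zero nodes remain reachable. With
#' `edges_per_step = 1` the result is a tree (exactly `n_nodes - 1` links,
#' single component). Higher `power` concentrates links on hubs.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param power preferential-attachment exponent (>= 0); 1 is classic linear
#'   preferential attachment.
#' @param edges_per_step links added per new node (>= 1).
#' @param seed optional integer seed; same seed gives the same topology.
#' @return an [as_adjacency()] matrix.
#' @export
generate_barabasi <- function(n_nodes, power = 1, edges_per_step = 1, seed = NULL) {
  if (length(n_nodes) != 1 || is.na(n_nodes) || n_nodes < 2)
    stop("n_nodes must be a single integer >= 2", call. = FALSE)
  if (power < 0) stop("power must be >= 0", call. = FALSE)
  if (edges_per_step < 1) stop("edges_per_step must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(n_nodes, power = power, m = edges_per_step,
                         zero.appeal = 1, directed = FALSE)
  mat <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
  mat[mat > 1] <- 1
  diag(mat) <- 0
  as_adjacency(mat, labels = paste0("gene", seq_len(n_nodes)))
}

#' Sample an Erdos-Renyi topology with a requested mean degree
#'
#' Draws a G(n, p) graph with `p = mean_degree / (n_nodes - 1)`, so the
#' expected mean degree equals the requested value. Disconnected samples are
#' kept as drawn.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param mean_degree requested expected mean degree, in `(0, n_nodes - 1]`.
#' @param seed optional integer seed.
#' @return an [as_adjacency()] matrix.
#' @export
generate_erdos_renyi <- function(n_nodes, mean_degree, seed = NULL) {
  if (length(n_nodes) != 1 || is.na(n_nodes) || n_nodes < 2)
    stop("n_nodes must be a single integer >= 2", call. = FALSE)
  if (mean_degree <= 0 || mean_degree > n_nodes - 1)
    stop("mean_degree must lie in (0, n_nodes - 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- mean_degree / (n_nodes - 1)
  g <- igraph::sample_gnp(n_nodes, p, directed = FALSE)
  mat <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
  as_adjacency(mat, labels = paste0("gene", seq_len(n_nodes)))
}

#' Network density as links over squared node count
#'
#' The density of a module is the ratio of the number of undirected links
#' (each symmetric pair counted once) to the square of the number of nodes,
#' `L / N^2`. Note this is not the usual edge density `L / (N(N-1)/2)`.
#'
#' @param adj an adjacency matrix (validated).
#' @return density in `[0, 1]`.
#' @export
network_density <- function(adj) {
  adj <- as_adjacency(adj)
  n <- ncol(adj)
  links <- sum(adj[upper.tri(adj)])
  links / n^2
}

#' Read and write adjacency matrices
#'
#' The matrix dialect is a square tab-separated file whose first row and first
#' column carry node labels and whose values are strictly `0`/`1`. The edge
#' list dialect has columns `source` and `target`, each undirected pair listed
#' once; isolated nodes are restored through the `nodes` argument.
#'
#' @param path file path.
#' @param format `"auto"` (default; sniffed from the header), `"matrix"` or
#'   `"edgelist"`.
#' @param nodes for edge lists, the full label vector (defaults to the labels
#'   seen in the file, losing isolated nodes).
#' @return an [as_adjacency()] matrix.
#' @export
read_adjacency <- function(path, format = c("auto", "matrix", "edgelist"), nodes = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^source\t", first)) "edgelist" else "matrix"
  }
  if (format == "edgelist") {
    el <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("source", "target") %in% names(el)))
      stop("edge list must have 'source' and 'target' columns", call. = FALSE)
    labels <- if (is.null(nodes)) sort(unique(c(el$source, el$target))) else nodes
    mat <- matrix(0L, length(labels), length(labels), dimnames = list(labels, labels))
    for (r in seq_len(nrow(el))) {
      i <- match(el$source[r], labels); j <- match(el$target[r], labels)
      if (is.na(i) || is.na(j))
        stop(sprintf("edge list row %d names a node outside 'nodes'", r), call. = FALSE)
      mat[i, j] <- 1L; mat[j, i] <- 1L
    }
    return(as_adjacency(mat, labels))
  }
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  mat <- as.matrix(tab)
  if (nrow(mat) != ncol(mat))
    stop(sprintf("adjacency file is not square: %d rows, %d columns", nrow(mat), ncol(mat)),
         call. = FALSE)
  as_adjacency(mat, labels = colnames(mat))
}

#' @param adj adjacency matrix to write.
#' @rdname read_adjacency
#' @export
write_adjacency <- function(adj, path, format = c("matrix", "edgelist")) {
  adj <- as_adjacency(adj)
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(adj, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    el <- data.frame(source = rownames(adj)[idx[, 1]], target = colnames(adj)[idx[, 2]])
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
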