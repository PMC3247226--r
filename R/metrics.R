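#' Confusion counts between two topologies
#'
#' Compares a predicted adjacency matrix against the true one over the
#' N(N-1)/2 unordered node pairs (the diagonal is excluded: self-regulation is
#' not inferred). Counts sum to the number of pairs.
#'
#' @param true_adj ground-truth adjacency matrix.
#' @param pred_adj predicted adjacency matrix of the same size.
#' @return an object of class `"confusion_counts"` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(true_adj, pred_adj) {
  true_adj <- as_adjacency(true_adj)
  pred_adj <- as_adjacency(pred_adj)
  if (ncol(true_adj) != ncol(pred_adj))
    stop("true and predicted matrices must have the same number of nodes", call. = FALSE)
  ut <- upper.tri(true_adj)
  tv <- unclass(true_adj)[ut]
  pv <- unclass(pred_adj)[ut]
  structure(list(tp = sum(tv == 1 & pv == 1),
                 fp = sum(tv == 0 & pv == 1),
                 tn = sum(tv == 0 & pv == 0),
                 fn = sum(tv == 1 & pv == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (recall %.3f, precision %.3f, MCC %.3f)\n",
              x$tp, x$fp, x$tn, x$fn, recall(x), precision(x), mcc(x)))
  invisible(x)
}

#' Recall, precision and the Matthews correlation coefficient
#'
#' Recall is the fraction of true interactions correctly inferred,
#' `TP / (TP + FN)`; precision the fraction of true interactions among all
#' inferred ones, `TP / (TP + FP)`. The MCC,
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, is a balanced score
#' in \[-1, 1\]: 1 for a perfect prediction, 0 for an average random one, -1
#' for an inverse prediction. Whenever a denominator factor is zero the score
#' is defined as 0 (no better than chance).
#'
#' @param counts a [confusion_counts()] object (or list with `tp`, `fp`, `tn`,
#'   `fn`).
#' @return a single number.
#' @export
recall <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0) 0 else counts$tp / d
}

#' @rdname recall
#' @export
precision <- function(counts) {
  d <- counts$tp + counts$fp
  if (d == 0) 0 else counts$tp / d
}

#' @rdname recall
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  f1 <- tp + fp; f2 <- tp + fn; f3 <- tn + fp; f4 <- tn + fn
  if (f1 == 0 || f2 == 0 || f3 == 0 || f4 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(f1 * f2 * f3 * f4)
}

#' Precision-recall and MCC-recall curves over the binarization threshold
#'
#' Sweeps `n_thresholds` evenly spaced thresholds from 0 to the maximum
#' observed pair strength, binarizes the score matrix at each, and records
#' recall, precision and MCC. The areas under the precision-recall (`auc_pr`)
#' and MCC-recall (`auc_mr`) curves are computed by the trapezoidal rule over
#' recall, after averaging duplicate-recall points and anchoring the endpoints
#' at recall 0 and 1 with the nearest computed value. A chance-level scorer
#' yields an MCC-recall AUC near 0; a perfect scorer near 1.
#'
#' @param true_adj ground-truth adjacency matrix.
#' @param scores correlation matrix of interaction scores.
#' @param n_thresholds number of thresholds (>= 2).
#' @inheritParams binarize
#' @return a tibble of class `"eval_curve"` with columns `threshold`,
#'   `recall`, `precision`, `mcc` and attributes `auc_pr`, `auc_mr` (see
#'   [glance.eval_curve()]).
#' @export
eval_curve <- function(true_adj, scores, n_thresholds = 100,
                       combine = "max", absolute = TRUE) {
  true_adj <- as_adjacency(true_adj)
  if (n_thresholds < 2) stop("n_thresholds must be >= 2", call. = FALSE)
  s <- pair_strength(scores, combine, absolute)
  smax <- max(s)
  if (smax == 0) {
    warning("all pair strengths are zero; degenerate single-point curve", call. = FALSE)
    pts <- tibble::tibble(threshold = 0, recall = 0, precision = 0, mcc = 0)
    return(new_eval_curve(pts, auc_pr = 0, auc_mr = 0))
  }
  thresholds <- seq(0, smax, length.out = n_thresholds)
  pts <- purrr::map_dfr(thresholds, function(t) {
    cc <- confusion_counts(true_adj, binarize_strength(s, t, colnames(true_adj)))
    tibble::tibble(threshold = t, recall = recall(cc),
                   precision = precision(cc), mcc = mcc(cc),
                   n_predicted = cc$tp + cc$fp)
  })
  # thresholds at/above the top strength predict nothing; such degenerate
  # points carry no information about the scorer and are excluded from the
  # integration (the PR-curve convention)
  informative <- pts[pts$n_predicted > 0, ]
  if (nrow(informative) == 0) informative <- pts
  new_eval_curve(pts,
                 auc_pr = auc_over_recall(informative$recall, informative$precision),
                 auc_mr = auc_over_recall(informative$recall, informative$mcc))
}

# binarize a precomputed strength matrix (thresholds may exceed 1 never; the
# strength of correlation scores is bounded by 1)
binarize_strength <- function(s, threshold, labels) {
  adj <- (s > threshold) * 1L
  diag(adj) <- 0L
  as_adjacency(adj, labels = labels %||% paste0("gene", seq_len(ncol(s))))
}

# trapezoidal AUC of value-vs-recall: average duplicate recalls, sort by
# recall, anchor the endpoints at recall 0 and 1 by carrying the nearest value
auc_over_recall <- function(rec, value) {
  agg <- tapply(value, rec, mean)
  r <- as.numeric(names(agg))
  v <- as.numeric(agg)
  o <- order(r)
  r <- r[o]; v <- v[o]
  if (r[1] > 0) { r <- c(0, r); v <- c(v[1], v) }
  n <- length(r)
  if (r[n] < 1) { r <- c(r, 1); v <- c(v, v[n]) }
  sum(diff(r) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

new_eval_curve <- function(pts, auc_pr, auc_mr) {
  out <- tibble::new_tibble(pts, auc_pr = auc_pr, auc_mr = auc_mr,
                            class = "eval_curve")
  out
}

#' @export
print.eval_curve <- function(x, ...) {
  cat(sprintf("evaluation curve: %d thresholds; AUC(PR) = %.3f, AUC(MR) = %.3f\n",
              nrow(x), attr(x, "auc_pr"), attr(x, "auc_mr")))
  NextMethod()
}

#' Tidy and summarize evaluation curves
#'
#' `tidy()` returns the per-threshold points; `glance()` the two AUC
#' summaries.
#'
#' @param x an [eval_curve()] object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.eval_curve <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.eval_curve
#' @export
glance.eval_curve <- function(x, ...) {
  tibble::tibble(auc_pr = attr(x, "auc_pr"), auc_mr = attr(x, "auc_mr"),
                 n_thresholds = nrow(x))
}

#' Plot an evaluation curve
#'
#' Precision-recall (solid) and MCC-recall (dashed) curves on one panel.
#'
#' @param object an [eval_curve()] object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eval_curve <- function(object, ...) {
  pts <- tidy.eval_curve(object)
  long <- tibble::tibble(
    recall = rep(pts$recall, 2),
    value = c(pts$precision, pts$mcc),
    curve = rep(c("precision", "MCC"), each = nrow(pts)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$recall, y = .data$value,
                                     linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(precision = "solid", MCC = "dashed")) +
    ggplot2::labs(x = "recall", y = "score",
                  title = sprintf("AUC(PR) = %.3f, AUC(MR) = %.3f",
                                  attr(object, "auc_pr"), attr(object, "auc_mr"))) +
    ggplot2::theme_minimal()
}

#' Grid search for the binarization threshold
#'
#' Evaluates the MCC of `binarize(scores, t)` against the true topology for
#' every threshold in `grid` and returns the maximizer; ties are broken toward
#' the smallest threshold.
#'
#' @inheritParams eval_curve
#' @param grid thresholds to evaluate (default 0 to 1 in steps of 0.01).
#' @return a one-row tibble with `best_threshold` and `best_mcc`.
#' @export
grid_search_threshold <- function(true_adj, scores, grid = seq(0, 1, by = 0.01),
                                  combine = "max", absolute = TRUE) {
  true_adj <- as_adjacency(true_adj)
  grid <- sort(grid)
  s <- pair_strength(scores, combine, absolute)
  mccs <- vapply(grid, function(t) {
    mcc(confusion_counts(true_adj, binarize_strength(s, t, colnames(true_adj))))
  }, numeric(1))
  best <- which.max(mccs)   # first maximum = smallest threshold on a sorted grid
  tibble::tibble(best_threshold = grid[best], best_mcc = mccs[best])
}
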