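#' Configure a repeated generate-infer-score protocol
#'
#' One protocol cell fixes a topology model, a network size, a data ratio (the
#' number of expression profiles divided by the number of genes), a
#' normalization scheme and the inference settings. Running the cell samples
#' `n_topologies` topologies and, for each, performs `n_data_repeats`
#' independent generate -> normalize -> infer -> score runs; every run has a
#' seed derived from `base_seed` so any cell can be replayed.
#'
#' Desk-scale defaults (5 data repeats, 3 topologies, small networks) keep a
#' full sweep tractable on one CPU.
#'
#' @param topology `"barabasi"` or `"erdos_renyi"`.
#' @param n_nodes number of genes in the network.
#' @param data_ratio samples per gene; the sample count is
#'   `round(data_ratio * n_nodes)` (> 0).
#' @param normalization scheme applied before inference: `"linear_rescaled"`,
#'   `"statistical"` or `"discretized"`. Schemes whose output is unbounded are
#'   linearly mapped into \[-1, 1\] afterwards, since the regressors' tanh
#'   outputs live there.
#' @param params [learning_params()] for the inference (its `seed` is
#'   overridden per run).
#' @param threshold binarization threshold for MCC scoring.
#' @param score `"mcc"` (fixed threshold) or `"auc_mr"` (threshold-free
#'   MCC-recall AUC).
#' @param power,edges_per_step Barabasi parameters.
#' @param mean_degree Erdos-Renyi parameter.
#' @param n_data_repeats independent data/inference repeats per topology (>= 1).
#' @param n_topologies independent topology samples (>= 1).
#' @param base_seed base of all derived seeds.
#' @return an object of class `"protocol_config"`.
#' @export
protocol_config <- function(topology = c("barabasi", "erdos_renyi"),
                            n_nodes = 20, data_ratio = 1,
                            normalization = c("linear_rescaled", "statistical",
                                              "discretized"),
                            params = learning_params(), threshold = 0.5,
                            score = c("mcc", "auc_mr"),
                            power = 1, edges_per_step = 1, mean_degree = 2,
                            n_data_repeats = 5, n_topologies = 3,
                            base_seed = 1) {
  topology <- match.arg(topology)
  normalization <- match.arg(normalization)
  score <- match.arg(score)
  if (data_ratio <= 0) stop("data_ratio must be > 0", call. = FALSE)
  if (n_data_repeats < 1) stop("n_data_repeats must be >= 1", call. = FALSE)
  if (n_topologies < 1) stop("n_topologies must be >= 1", call. = FALSE)
  structure(list(topology = topology, n_nodes = n_nodes, data_ratio = data_ratio,
                 normalization = normalization, params = params,
                 threshold = threshold, score = score, power = power,
                 edges_per_step = edges_per_step, mean_degree = mean_degree,
                 n_data_repeats = n_data_repeats, n_topologies = n_topologies,
                 base_seed = as.integer(base_seed)),
            class = "protocol_config")
}

sample_topology <- function(cfg, seed) {
  switch(cfg$topology,
    barabasi = generate_barabasi(cfg$n_nodes, power = cfg$power,
                                 edges_per_step = cfg$edges_per_step, seed = seed),
    erdos_renyi = generate_erdos_renyi(cfg$n_nodes, cfg$mean_degree, seed = seed))
}

apply_normalization <- function(expr, scheme) {
  out <- switch(scheme,
    linear_rescaled = rescale_linear(expr),
    statistical = normalize_statistical(expr),
    discretized = discretize_signs(expr))
  # the regressors take inputs/targets in [-1, 1]; map unbounded schemes there
  # (affine per column, so the studied normalization's structure is preserved)
  if (max(abs(unclass(out))) > 1 + 1e-8) {
    vals <- rescale_linear(out)
    attr(vals, "normalization") <- scheme
    out <- vals
  }
  out
}

score_prediction <- function(cfg, truth, scores) {
  if (cfg$score == "mcc") {
    mcc(confusion_counts(truth, binarize(scores, cfg$threshold)))
  } else {
    attr(eval_curve(truth, scores), "auc_mr")
  }
}

#' Run one protocol cell
#'
#' For each sampled topology, repeats the generate -> normalize -> infer ->
#' score pipeline and reports the per-topology mean score with its error
#' (twice the standard deviation), plus the grand mean over all runs. A run
#' that errors is recorded with its seed (score `NA`) so it can be replayed;
#' it does not abort the other runs.
#'
#' @param cfg a [protocol_config()].
#' @param scorer optional replacement for the inference step, a function
#'   `(expr, truth, params) -> correlation matrix`; used for oracle and null
#'   scorers when testing the protocol plumbing itself. Default uses
#'   [infer_network()].
#' @return an object of class `"protocol_result"`: a list with `raw` (one row
#'   per run: topology, repeat, seed, score, error message if any), `summary`
#'   (per-topology mean and `error = 2 * sd`) and `config`.
#' @export
run_protocol <- function(cfg, scorer = NULL) {
  stopifnot(inherits(cfg, "protocol_config"))
  m <- max(1L, as.integer(round(cfg$data_ratio * cfg$n_nodes)))
  raw <- purrr::map_dfr(seq_len(cfg$n_topologies), function(t) {
    topo_seed <- cfg$base_seed + 1000L * t
    truth <- sample_topology(cfg, topo_seed)
    purrr::map_dfr(seq_len(cfg$n_data_repeats), function(r) {
      run_seed <- topo_seed + r
      res <- tryCatch({
        expr <- generate_slc(truth, m, seed = run_seed)
        expr <- apply_normalization(expr, cfg$normalization)
        run_params <- cfg$params
        run_params$seed <- run_seed
        scores <- if (is.null(scorer)) infer_network(expr, run_params)
                  else scorer(expr, truth, run_params)
        list(score = score_prediction(cfg, truth, scores), error = NA_character_)
      }, error = function(e) list(score = NA_real_, error = conditionMessage(e)))
      tibble::tibble(topology = t, data_repeat = r, seed = run_seed,
                     score = res$score, error_message = res$error)
    })
  })
  summary <- raw |>
    dplyr::group_by(.data$topology) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_score = mean(.data$score, na.rm = TRUE),
      error = 2 * stats::sd(.data$score, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(error = ifelse(is.na(.data$error), 0, .data$error))
  structure(list(raw = raw, summary = summary, config = cfg),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  g <- glance.protocol_result(x)
  cat(sprintf("protocol: %s, %d nodes, data ratio %g, %s, score = %s\n",
              x$config$topology, x$config$n_nodes, x$config$data_ratio,
              x$config$normalization, x$config$score))
  cat(sprintf("grand mean %s = %.3f +/- %.3f (2 SD) over %d runs\n",
              x$config$score, g$mean_score, g$error, g$n_runs))
  invisible(x)
}

#' Tidy and summarize protocol results
#'
#' `tidy()` returns the per-run raw scores; `glance()` the grand mean, the
#' error (twice the standard deviation over all runs) and run counts.
#'
#' @param x a [run_protocol()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.protocol_result <- function(x, ...) x$raw

#' @rdname tidy.protocol_result
#' @export
glance.protocol_result <- function(x, ...) {
  ok <- x$raw$score[!is.na(x$raw$score)]
  tibble::tibble(mean_score = mean(ok),
                 error = if (length(ok) > 1) 2 * stats::sd(ok) else 0,
                 n_runs = nrow(x$raw),
                 n_failed = sum(is.na(x$raw$score)),
                 score = x$config$score)
}

#' Plot per-topology protocol scores
#' @param object a [run_protocol()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.protocol_result <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$topology), y = .data$mean_score)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_score - .data$error,
                                          ymax = .data$mean_score + .data$error)) +
    ggplot2::labs(x = "topology sample", y = object$config$score) +
    ggplot2::theme_minimal()
}

#' Sweep a grid of protocol configurations
#'
#' Runs each cell and binds the results into a long table suitable for
#' plotting score against the swept factor (data ratio, node count, mean
#' degree, power-law exponent, normalization, learning parameters). A cell
#' that errors is recorded with `NA` scores and does not abort the sweep.
#'
#' @param cfgs list of [protocol_config()] objects.
#' @param scorer optional scorer override (see [run_protocol()]).
#' @return a tibble of class `"protocol_sweep"`, one row per cell, with the
#'   cell's factors, the grand `mean_score` and `error` (2 SD), and the full
#'   `protocol_result` in a list-column.
#' @export
sweep_protocols <- function(cfgs, scorer = NULL) {
  stopifnot(length(cfgs) >= 1)
  rows <- purrr::map_dfr(seq_along(cfgs), function(i) {
    cfg <- cfgs[[i]]
    res <- tryCatch(run_protocol(cfg, scorer = scorer), error = function(e) e)
    failed <- inherits(res, "error")
    g <- if (failed) tibble::tibble(mean_score = NA_real_, error = NA_real_,
                                    n_runs = 0L, n_failed = NA_integer_,
                                    score = cfg$score)
         else glance.protocol_result(res)
    tibble::tibble(cell = i, topology = cfg$topology, n_nodes = cfg$n_nodes,
                   data_ratio = cfg$data_ratio,
                   normalization = cfg$normalization,
                   power = cfg$power, mean_degree = cfg$mean_degree,
                   learning_rate = cfg$params$learning_rate,
                   momentum = cfg$params$momentum, epochs = cfg$params$epochs,
                   score_kind = g$score, mean_score = g$mean_score,
                   error = g$error, n_runs = g$n_runs,
                   result = list(if (failed) res else res))
  })
  tibble::new_tibble(rows, class = "protocol_sweep")
}

#' Plot a protocol sweep against a chosen factor
#' @param object a [sweep_protocols()] table.
#' @param x name of the swept column (default `"data_ratio"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.protocol_sweep <- function(object, x = "data_ratio", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x]], y = .data$mean_score,
                                       colour = .data$topology)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_score - .data$error,
                                          ymax = .data$mean_score + .data$error)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = unique(object$score_kind)[1]) +
    ggplot2::theme_minimal()
}

#' Train/validation study of the binarization threshold
#'
#' Repeats `n_splits` random sample-wise partitions of the expression data
#' (the topology is fixed): scores are inferred on the training half, the
#' threshold maximizing the training MCC is found by grid search, and the
#' inference on the validation half is scored at that threshold.
#'
#' @param expr expression matrix, linearly rescaled.
#' @param true_adj ground-truth adjacency matrix.
#' @param n_splits number of random partitions (>= 1).
#' @param split_fraction fraction of samples assigned to training, in (0, 1);
#'   both halves must be non-empty.
#' @param grid threshold grid (see [grid_search_threshold()]).
#' @param params [learning_params()] for the inference.
#' @param scorer optional scorer override `(expr, truth, params) -> scores`.
#' @param seed base seed for the partitions.
#' @return a tibble with one row per split: `split`, `best_threshold`,
#'   `train_mcc`, `validation_mcc`; means and `2 * sd` are available through
#'   standard summaries.
#' @export
threshold_study <- function(expr, true_adj, n_splits = 10, split_fraction = 0.5,
                            grid = seq(0, 1, by = 0.01),
                            params = learning_params(), scorer = NULL,
                            seed = 1) {
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (n_splits < 1) stop("n_splits must be >= 1", call. = FALSE)
  true_adj <- as_adjacency(true_adj)
  m <- nrow(expr)
  n_train <- round(split_fraction * m)
  if (n_train < 1 || n_train >= m)
    stop("degenerate split: both halves must contain at least one sample", call. = FALSE)
  infer <- function(e, run_params) {
    if (is.null(scorer)) infer_network(e, run_params)
    else scorer(e, true_adj, run_params)
  }
  purrr::map_dfr(seq_len(n_splits), function(sp) {
    set.seed(seed + sp)
    idx <- sample.int(m, n_train)
    run_params <- params
    run_params$seed <- seed + sp
    train_scores <- infer(expr[idx, , drop = FALSE], run_params)
    best <- grid_search_threshold(true_adj, train_scores, grid)
    val_scores <- infer(expr[-idx, , drop = FALSE], run_params)
    val_mcc <- mcc(confusion_counts(true_adj,
                                    binarize(val_scores, best$best_threshold)))
    tibble::tibble(split = sp, best_threshold = best$best_threshold,
                   train_mcc = best$best_mcc, validation_mcc = val_mcc)
  })
}
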