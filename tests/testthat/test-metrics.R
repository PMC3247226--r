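test_that("confusion counts agree with brute-force pair enumeration", {
  set.seed(17)
  for (i in 1:20) {
    truth <- rand_adjacency(6, runif(1, 0.2, 0.6))
    pred <- rand_adjacency(6, runif(1, 0.2, 0.6))
    got <- confusion_counts(truth, pred)
    want <- ref_confusion(truth, pred)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$tn, want$tn)
    expect_equal(got$fn, want$fn)
    expect_equal(got$tp + got$fp + got$tn + got$fn, 15)  # 6*5/2 pairs
  }

  truth <- rand_adjacency(6, 0.4)
  same <- confusion_counts(truth, truth)
  expect_equal(same$fp + same$fn, 0)
  comp <- 1 - truth; diag(comp) <- 0
  inv <- confusion_counts(truth, comp)
  expect_equal(inv$tp + inv$tn, 0)
  expect_error(confusion_counts(truth, rand_adjacency(5)), "same number")
})

test_that("scores match direct formulas on all small confusion tables", {
  for (tp in 0:3) for (fp in 0:3) for (tn in 0:3) for (fn in 0:3) {
    counts <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
                        class = "confusion_counts")
    expect_equal(recall(counts), if (tp + fn == 0) 0 else tp / (tp + fn))
    expect_equal(precision(counts), if (tp + fp == 0) 0 else tp / (tp + fp))
    expect_equal(mcc(counts), ref_mcc(tp, fp, tn, fn))
  }
})

test_that("MCC hits 1 / -1 on perfect / inverse predictions and respects its symmetries", {
  cc <- structure(list(tp = 5, fp = 0, tn = 7, fn = 0), class = "confusion_counts")
  expect_equal(mcc(cc), 1)
  expect_equal(recall(cc), 1)
  expect_equal(precision(cc), 1)
  inv <- structure(list(tp = 0, fp = 7, tn = 0, fn = 5), class = "confusion_counts")
  expect_equal(mcc(inv), -1)

  set.seed(23)
  for (i in 1:50) {
    v <- as.list(sample(0:9, 4, replace = TRUE))
    names(v) <- c("tp", "fp", "tn", "fn")
    swapped <- list(tp = v$tn, fp = v$fn, tn = v$tp, fn = v$fp)
    negated <- list(tp = v$fp, fp = v$tp, tn = v$fn, fn = v$tn)
    expect_equal(mcc(v), mcc(swapped))
    expect_equal(mcc(v), -mcc(negated))
  }
})

test_that("random predictions on random truths average to chance-level MCC", {
  set.seed(29)
  vals <- replicate(2000, {
    mcc(confusion_counts(rand_adjacency(8, 0.4), rand_adjacency(8, 0.4)))
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("a perfect scorer yields MCC 1 at interior thresholds and unit AUC", {
  set.seed(3)
  truth <- as_adjacency(rand_adjacency(8, 0.4))
  scores <- unclass(truth) * 1.0
  cv <- eval_curve(truth, scores, n_thresholds = 21)
  inner <- cv$threshold > 0 & cv$threshold < 1
  expect_true(all(cv$mcc[cv$n_predicted > 0] == 1))
  expect_true(any(inner))
  expect_equal(attr(cv, "auc_mr"), 1)
  expect_equal(attr(cv, "auc_pr"), 1)
})

test_that("curve recall never increases with the threshold", {
  set.seed(37)
  for (i in 1:10) {
    truth <- as_adjacency(rand_adjacency(10, 0.3))
    cv <- eval_curve(truth, rand_scores(10), n_thresholds = 30)
    expect_true(all(diff(cv$recall) <= 1e-12))
    expect_true(all(diff(cv$threshold) > 0))
  }
})

test_that("chance-level scorers have MCC-recall AUC near zero", {
  set.seed(41)
  aucs <- replicate(100, {
    truth <- as_adjacency(rand_adjacency(12, 0.3))
    attr(eval_curve(truth, rand_scores(12), n_thresholds = 40), "auc_mr")
  })
  expect_lt(abs(mean(aucs)), 0.03)
})

test_that("trapezoidal AUC agrees with a refined Riemann-sum oracle", {
  # midpoint Riemann sum on a 10x-refined grid over the same aggregated curve
  riemann_auc <- function(rec, val, refine = 10) {
    agg <- tapply(val, rec, mean)
    r <- as.numeric(names(agg)); v <- as.numeric(agg)
    o <- order(r); r <- r[o]; v <- v[o]
    if (r[1] > 0) { r <- c(0, r); v <- c(v[1], v) }
    if (r[length(r)] < 1) { r <- c(r, 1); v <- c(v, v[length(v)]) }
    total <- 0
    for (i in seq_len(length(r) - 1)) {
      width <- (r[i + 1] - r[i]) / refine
      if (width == 0) next
      mids <- r[i] + (seq_len(refine) - 0.5) * width
      vm <- v[i] + (mids - r[i]) / (r[i + 1] - r[i]) * (v[i + 1] - v[i])
      total <- total + sum(vm * width)
    }
    total
  }
  set.seed(43)
  for (i in 1:10) {
    truth <- as_adjacency(rand_adjacency(10, 0.35))
    cv <- eval_curve(truth, rand_scores(10), n_thresholds = 50)
    pts <- cv[cv$n_predicted > 0, ]
    expect_equal(attr(cv, "auc_mr"), riemann_auc(pts$recall, pts$mcc),
                 tolerance = 1e-3)
    expect_equal(attr(cv, "auc_pr"), riemann_auc(pts$recall, pts$precision),
                 tolerance = 1e-3)
  }
})

test_that("degrading a perfect scorer never raises the MCC-recall AUC", {
  set.seed(47)
  truth <- as_adjacency(rand_adjacency(10, 0.3))
  scores <- unclass(truth) * 1.0
  base <- attr(eval_curve(truth, scores, n_thresholds = 30), "auc_mr")
  links <- which(upper.tri(scores) & scores == 1)
  for (k in seq_along(links)) {
    s <- scores
    drop_idx <- links[seq_len(k)]
    s[drop_idx] <- 0
    s <- pmin(s, t(s))  # keep symmetric
    # dropping the last link leaves an all-zero matrix, whose degenerate-curve
    # warning is covered by its own test below
    cv <- suppressWarnings(eval_curve(truth, s, n_thresholds = 30))
    expect_lte(attr(cv, "auc_mr"), base + 1e-12)
  }
})

test_that("an all-zero score matrix degenerates with a warning", {
  truth <- as_adjacency(rand_adjacency(5, 0.4))
  expect_warning(cv <- eval_curve(truth, matrix(0, 5, 5)), "zero")
  expect_equal(attr(cv, "auc_mr"), 0)
  expect_equal(attr(cv, "auc_pr"), 0)
})

test_that("threshold grid search maximizes MCC with smallest-threshold ties", {
  set.seed(53)
  truth <- as_adjacency(rand_adjacency(8, 0.4))
  perfect <- unclass(truth) * 1.0
  best <- grid_search_threshold(truth, perfect, grid = seq(0.1, 0.9, by = 0.1))
  expect_equal(best$best_mcc, 1)
  expect_equal(best$best_threshold, 0.1)

  zero <- grid_search_threshold(truth, matrix(0, 8, 8), grid = seq(0.1, 0.9, by = 0.1))
  expect_equal(zero$best_mcc, 0)
  expect_equal(zero$best_threshold, 0.1)

  scores <- rand_scores(8)
  grid <- seq(0, 1, by = 0.05)
  got <- grid_search_threshold(truth, scores, grid)
  want <- vapply(grid, function(t) {
    mcc(confusion_counts(truth, binarize(scores, t)))
  }, numeric(1))
  expect_equal(got$best_mcc, max(want))
  expect_equal(got$best_threshold, grid[which.max(want)])
})

test_that("curves expose tidy, glance and a plot", {
  set.seed(59)
  truth <- as_adjacency(rand_adjacency(6, 0.4))
  cv <- eval_curve(truth, rand_scores(6), n_thresholds = 10)
  td <- tidy(cv)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10)
  g <- glance(cv)
  expect_named(g, c("auc_pr", "auc_mr", "n_thresholds"))
  expect_s3_class(autoplot(cv), "ggplot")
})
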