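small_cfg <- function(max_epochs = 40, patience = 40, ...) {
  run_config(num_filters = 8, max_epochs = max_epochs, patience = patience,
             seed = 1, attention_reduction = 4, ...)
}

test_that("metrics match brute-force oracles on random vectors", {
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    p <- runif(n)
    if (rep %% 5 == 0) p <- round(p, 1)  # exercise ties
    m <- compute_metrics(y, p)
    expect_equal(m$auroc, auroc_pairs(y, p), tolerance = 1e-10)
    expect_equal(m$aupr, aupr_thresholds(y, p), tolerance = 1e-10)
    tp <- sum(p >= 0.5 & y == 1); tn <- sum(p < 0.5 & y == 0)
    fp <- sum(p >= 0.5 & y == 0); fn <- sum(p < 0.5 & y == 1)
    expect_equal(m$mcc, mcc_direct(tp, tn, fp, fn), tolerance = 1e-10)
  }
})

test_that("metric edge cases behave as specified", {
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(.9, .8, .4, .2))$auroc, 1.0)
  expect_equal(compute_metrics(c(1, 0, 1, 0), rep(0.3, 4))$auroc, 0.5)
  # TP=2 TN=3 FP=1 FN=0 -> MCC = 6/sqrt(72)
  m <- compute_metrics(c(1, 1, 0, 0, 0, 0), c(.9, .8, .7, .2, .1, .1))
  expect_equal(m$mcc, 6 / sqrt(72), tolerance = 1e-10)
  expect_error(compute_metrics(c(1, 1), c(.2, .3)), "one class")
})

test_that("training is seeded-reproducible and stops within patience", {
  ds <- toy_dataset(n = 40, f = 5, shift = 1.5, seed = 13)
  cfg <- small_cfg(max_epochs = 60, patience = 10)
  fit1 <- train_mdignn(ds$graph, ds$features, ds$labels, cfg)
  fit2 <- train_mdignn(ds$graph, ds$features, ds$labels, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_lte(fit1$stopped_epoch - fit1$best_epoch, cfg$patience)
  expect_equal(fit1$history$val_loss[fit1$best_epoch],
               min(fit1$history$val_loss))
})

test_that("training refuses a mask without positive labels", {
  ds <- toy_dataset(n = 30, f = 4, seed = 14)
  cfg <- small_cfg(max_epochs = 3)
  expect_error(
    train_mdignn(ds$graph, ds$features, ds$labels, cfg,
                 train_genes = ds$neg[1:10], val_genes = ds$neg[11:15]),
    "no positive")
})

test_that("loss decreases on planted-signal data", {
  ds <- toy_dataset(n = 50, f = 6, shift = 2, seed = 15)
  cfg <- small_cfg(max_epochs = 50, patience = 50, edge_dropout = 0,
                   dropout = 0)
  fit <- train_mdignn(ds$graph, ds$features, ds$labels, cfg)
  h <- fit$history$train_loss
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))
})

test_that("edge dropout re-samples the operator only when enabled", {
  ds <- toy_dataset(n = 30, f = 4, shift = 1, seed = 16)
  cfg0 <- small_cfg(max_epochs = 5, edge_dropout = 0, dropout = 0)
  f1 <- train_mdignn(ds$graph, ds$features, ds$labels, cfg0)
  f2 <- train_mdignn(ds$graph, ds$features, ds$labels, cfg0)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  cfgd <- small_cfg(max_epochs = 5, edge_dropout = 0.3, dropout = 0)
  f3 <- train_mdignn(ds$graph, ds$features, ds$labels, cfgd)
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("cross-validation emits one row per fold per repeat", {
  ds <- toy_dataset(n = 50, f = 5, shift = 2, seed = 17, n_pos = 10,
                    n_neg = 20)
  cfg <- small_cfg(max_epochs = 5, patience = 5)
  rep2 <- cross_validate(ds$graph, ds$features, ds$labels, cfg,
                         n_folds = 5, n_repeats = 2)
  expect_equal(nrow(rep2$per_fold), 10)
  expect_equal(sort(unique(rep2$per_fold$fold)), 1:5)
  # every labeled gene tested exactly once per repeat
  expect_error(cross_validate(ds$graph, ds$features,
                              label_set(ds$pos[1:3], ds$neg, ds$graph),
                              cfg, n_folds = 5),
               "at least 5")
})

test_that("ranking partitions candidates into known and novel", {
  ds <- toy_dataset(n = 40, f = 5, shift = 2.5, seed = 18)
  cfg <- small_cfg(max_epochs = 30, patience = 30)
  fit <- train_mdignn(ds$graph, ds$features, ds$labels, cfg)
  tbl <- rank_candidates(fit, ds$graph, ds$features, ds$labels,
                         threshold = 0.9)
  expect_equal(nrow(tbl), 40)
  expect_equal(tbl$rank, 1:40)
  expect_true(all(tbl$probability > 0 & tbl$probability < 1))
  expect_true(all(tbl$probability[tbl$candidate] > 0.9))
  expect_true(all(!tbl$novel[tbl$label_status == "positive"]))
  expect_setequal(tbl$gene[tbl$novel],
                  tbl$gene[tbl$candidate & tbl$label_status != "positive"])
  # threshold 1 empties the candidate set (sigmoid < 1)
  tbl1 <- rank_candidates(fit, ds$graph, ds$features, ds$labels, threshold = 1)
  expect_equal(sum(tbl1$candidate), 0)
  # manual threshold semantics on a known probability vector
  probs <- c(A = .95, B = .91, C = .5)
  expect_equal(sum(probs > 0.9), 2)
})

test_that("no test-fold leakage: standardization and folds are label-free", {
  # fold assignment depends only on the repeat seed, never on features
  ds <- toy_dataset(n = 30, f = 3, seed = 19)
  y <- rep(NA_real_, 30)
  y[match(ds$labels$positives, ds$graph$nodes)] <- 1
  y[match(ds$labels$negatives, ds$graph$nodes)] <- 0
  ids <- which(!is.na(y))
  set.seed(0)
  f1 <- mdignn:::fold_assignment(ids, y, 5)
  set.seed(0)
  f2 <- mdignn:::fold_assignment(ids, y, 5)
  expect_identical(f1, f2)
  expect_setequal(unlist(f1), ids)
  # each fold is stratified: positive counts differ by at most one
  npos <- vapply(f1, function(v) sum(y[v] == 1), numeric(1))
  expect_lte(diff(range(npos)), 1)
})
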