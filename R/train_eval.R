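## Full-batch semi-supervised training with class-weighted binary
## cross-entropy, per-epoch edge dropout (the directed edge set is
## re-sampled and the operator rebuilt each epoch; evaluation always uses
## the full operator), Adam, and early stopping on validation loss.

clamp_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

weighted_bce <- function(prob, y, ids, pos_weight) {
  p <- clamp_prob(prob[ids])
  yy <- y[ids]
  w <- ifelse(yy == 1, pos_weight, 1)
  -sum(w * (yy * log(p) + (1 - yy) * log(1 - p))) / sum(w)
}

bce_grad_logits <- function(prob, y, ids, pos_weight, n) {
  yy <- y[ids]
  w <- ifelse(yy == 1, pos_weight, 1)
  g <- numeric(n)
  g[ids] <- w * (clamp_prob(prob[ids]) - yy) / sum(w)
  g
}

split_stratified <- function(ids, y, frac) {
  # deterministic given the current RNG stream; frac goes to the second part
  pos <- ids[y[ids] == 1]
  neg <- ids[y[ids] == 0]
  take <- function(v) {
    k <- max(1L, round(length(v) * frac))
    sample(v, k)
  }
  held <- c(take(pos), take(neg))
  list(train = setdiff(ids, held), val = held)
}

#' Train the model on one labeled split
#'
#' Full-batch training with Adam (learning rate and weight decay from the
#' config), class-weighted binary cross-entropy over the training nodes
#' (positive-class weight = #negatives / #positives in the training mask),
#' per-epoch edge dropout, and early stopping: training halts when the
#' validation loss has not improved for `patience` consecutive epochs, and
#' the parameters from the best validation epoch are returned. Unlabeled
#' nodes never enter the loss. Fully reproducible under `config$seed`.
#'
#' @param graph a [gene_graph()].
#' @param features a [feature_matrix()] aligned to `graph$nodes`
#'   (standardized).
#' @param labels a `label_set`.
#' @param config a [run_config()].
#' @param train_genes,val_genes disjoint character vectors of labeled genes;
#'   when `NULL`, a stratified 90/10 split of all labeled genes is drawn.
#' @return object of class `mdignn_fit`: list with `params`, `history`
#'   (epoch, train_loss, val_loss), `best_epoch`, `stopped_epoch`, `config`.
#' @export
train_mdignn <- function(graph, features, labels, config = run_config(),
                         train_genes = NULL, val_genes = NULL) {
  stopifnot(identical(rownames(features$values), graph$nodes))
  n <- n_nodes(graph)
  y <- rep(NA_real_, n)
  y[match(labels$positives, graph$nodes)] <- 1
  y[match(labels$negatives, graph$nodes)] <- 0
  set.seed(config$seed)
  if (is.null(train_genes)) {
    sp <- split_stratified(which(!is.na(y)), y, 0.1)
    train_ids <- sp$train
    val_ids <- sp$val
  } else {
    if (length(intersect(train_genes, val_genes))) {
      stop("train and validation gene sets overlap")
    }
    train_ids <- match(intersect(train_genes, graph$nodes), graph$nodes)
    val_ids <- match(intersect(val_genes, graph$nodes), graph$nodes)
  }
  n_pos <- sum(y[train_ids] == 1)
  n_neg <- sum(y[train_ids] == 0)
  if (n_pos == 0) stop("no positive labels in the training mask")
  pos_weight <- if (n_pos > 0) n_neg / n_pos else 1
  params <- init_model_params(config, ncol(features$values))
  state <- adam_init(params)
  pairs <- edge_index(graph)
  Lt_full <- lap_tilde_dense(pairs, n, config$q)
  X <- features$values
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  hist_epoch <- integer()
  hist_train <- numeric()
  hist_val <- numeric()
  for (epoch in seq_len(config$max_epochs)) {
    Lt <- if (config$edge_dropout > 0 && nrow(pairs)) {
      keep <- runif(nrow(pairs)) >= config$edge_dropout
      lap_tilde_dense(pairs[keep, , drop = FALSE], n, config$q)
    } else Lt_full
    fw <- mdignn_forward(params, X, Lt, config, train = TRUE)
    train_loss <- weighted_bce(fw$prob, y, train_ids, pos_weight)
    gl <- bce_grad_logits(fw$prob, y, train_ids, pos_weight, n)
    grads <- mdignn_backward(params, fw$cache, gl, config, Lt)
    upd <- adam_step(params, grads, state, config$lr, config$weight_decay)
    params <- upd$params
    state <- upd$state
    ev <- mdignn_forward(params, X, Lt_full, config, train = FALSE)
    val_loss <- weighted_bce(ev$prob, y, val_ids, pos_weight)
    hist_epoch[epoch] <- epoch
    hist_train[epoch] <- train_loss
    hist_val[epoch] <- val_loss
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      best_params <- params
      best_epoch <- epoch
    }
    if (epoch - best_epoch >= config$patience) break
  }
  structure(list(params = best_params, config = config,
                 history = data.frame(epoch = hist_epoch,
                                      train_loss = hist_train,
                                      val_loss = hist_val),
                 best_epoch = best_epoch,
                 stopped_epoch = length(hist_epoch),
                 train_genes = graph$nodes[train_ids],
                 val_genes = graph$nodes[val_ids]),
            class = "mdignn_fit")
}

#' @export
print.mdignn_fit <- function(x, ...) {
  cat(sprintf("<mdignn_fit> stopped at epoch %d (best validation epoch %d, loss %.4f)\n",
              x$stopped_epoch, x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}

#' Score every gene with a trained model
#'
#' Deterministic evaluation-mode forward pass on the full operator.
#'
#' @param fit an `mdignn_fit` (or a parameter list, with `config` supplied).
#' @param graph,features as in [train_mdignn()].
#' @param config required when `fit` is a bare parameter list.
#' @return named numeric vector of driver probabilities.
#' @export
predict_mdignn <- function(fit, graph, features, config = NULL) {
  if (inherits(fit, "mdignn_fit")) {
    params <- fit$params
    config <- fit$config
  } else {
    params <- fit
    if (is.null(config)) stop("config required when passing bare parameters")
  }
  Lt <- lap_tilde_dense(edge_index(graph), n_nodes(graph), config$q)
  prob <- mdignn_forward(params, features$values, Lt, config,
                         train = FALSE)$prob
  names(prob) <- graph$nodes
  prob
}

#' Classification metrics for one prediction vector
#'
#' AUROC by the rank statistic (ties get average ranks), AUPR by
#' step-integration of the precision-recall curve, and thresholded
#' confusion-matrix metrics: accuracy, sensitivity, specificity, precision
#' and MCC (0 when a denominator factor is 0).
#'
#' @param y_true 0/1 vector (both classes must be present).
#' @param y_prob predicted probabilities.
#' @param threshold classification threshold for the confusion-matrix
#'   metrics.
#' @return one-row data.frame with columns auroc, aupr, accuracy,
#'   sensitivity, specificity, precision, mcc.
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_prob), all(y_true %in% c(0, 1)))
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC/AUPR undefined: only one class present")
  r <- rank(y_prob)
  auroc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # step integration over distinct thresholds (tie-safe)
  ord <- order(-y_prob)
  tp_cum <- cumsum(y_true[ord] == 1)
  last <- rev(!duplicated(rev(y_prob[ord])))  # last index of each tie group
  tp <- tp_cum[last]
  rec <- tp / n1
  prec <- tp / which(last)
  aupr <- sum(diff(c(0, rec)) * prec)
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  data.frame(auroc = auroc, aupr = aupr,
             accuracy = (tp + tn) / length(y_true),
             sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
             specificity = if (tn + fp == 0) 0 else tn / (tn + fp),
             precision = if (tp + fp == 0) 0 else tp / (tp + fp),
             mcc = mcc)
}

fold_assignment <- function(ids, y, n_folds) {
  # stratified: shuffle each class, deal into folds round-robin
  f <- integer(length(ids))
  names(f) <- as.character(ids)
  for (cls in c(1, 0)) {
    v <- sample(ids[y[ids] == cls])
    f[as.character(v)] <- rep(seq_len(n_folds), length.out = length(v))
  }
  split(ids, f[as.character(ids)])
}

#' Repeated stratified cross-validation
#'
#' The labeled genes are split into `n_folds` stratified folds; each fold
#' serves once as the 20% test set while the remaining 80% train the model,
#' with a stratified 10% of the training labels held out for early
#' stopping. The procedure is repeated `n_repeats` times with fold
#' assignments seeded 0 .. n_repeats - 1, giving `n_folds * n_repeats`
#' per-fold metric rows, summarized as mean and sd.
#'
#' @param graph,features,labels,config as in [train_mdignn()].
#' @param n_folds number of CV folds.
#' @param n_repeats number of repetitions.
#' @return object of class `metrics_report`: list with `per_fold`
#'   (data.frame with `repetition`, `fold` and one column per metric) and
#'   `summary` (mean and sd rows).
#' @export
cross_validate <- function(graph, features, labels, config = run_config(),
                           n_folds = 5, n_repeats = 10) {
  labeled <- c(labels$positives, labels$negatives)
  n <- n_nodes(graph)
  y <- rep(NA_real_, n)
  y[match(labels$positives, graph$nodes)] <- 1
  y[match(labels$negatives, graph$nodes)] <- 0
  ids <- which(!is.na(y))
  if (length(labels$positives) < n_folds || length(labels$negatives) < n_folds) {
    stop(sprintf("each class needs at least %d members for %d-fold CV",
                 n_folds, n_folds))
  }
  rows <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(r - 1)
    folds <- fold_assignment(ids, y, n_folds)
    for (k in seq_len(n_folds)) {
      test_ids <- folds[[k]]
      trainval_ids <- setdiff(ids, test_ids)
      sp <- split_stratified(trainval_ids, y, 0.1)
      cfg <- config
      cfg$seed <- config$seed + (r - 1) * n_folds + (k - 1)
      fit <- train_mdignn(graph, features, labels, cfg,
                          train_genes = graph$nodes[sp$train],
                          val_genes = graph$nodes[sp$val])
      prob <- predict_mdignn(fit, graph, features)
      m <- compute_metrics(y[test_ids], prob[test_ids])
      rows[[length(rows) + 1]] <- cbind(data.frame(repetition = r, fold = k), m)
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), c("repetition", "fold"))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(per_fold[metric_cols], mean, numeric(1)),
    sd = vapply(per_fold[metric_cols], sd, numeric(1)),
    row.names = NULL)
  structure(list(per_fold = per_fold, summary = summary,
                 n_folds = n_folds, n_repeats = n_repeats),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d folds x %d repeats (mean +/- sd)\n",
              x$n_folds, x$n_repeats))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Rank genes and flag novel driver candidates
#'
#' Scores every node with a model trained on the entire labeled set, ranks
#' by probability (descending; alphabetical within ties) and partitions the
#' high-scoring set: genes with probability above `threshold` are
#' candidates, and candidates outside the known positive set are novel.
#'
#' @param fit a trained `mdignn_fit` (e.g. from [train_mdignn()] on all
#'   labeled genes).
#' @param graph,features,labels as in [train_mdignn()].
#' @param threshold candidate probability cutoff.
#' @return data.frame (class `prediction_table`) with columns gene,
#'   probability, label_status, rank, candidate, novel; sorted by rank.
#' @export
rank_candidates <- function(fit, graph, features, labels, threshold = 0.9) {
  prob <- predict_mdignn(fit, graph, features)
  df <- data.frame(gene = graph$nodes, probability = unname(prob),
                   label_status = label_status(labels, graph$nodes),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$probability, df$gene), ]
  df$rank <- seq_len(nrow(df))
  df$candidate <- df$probability > threshold
  df$novel <- df$candidate & df$label_status != "positive"
  rownames(df) <- NULL
  class(df) <- c("prediction_table", "data.frame")
  df
}
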