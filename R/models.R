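# Classifier families: 1-nearest-neighbor on an arbitrary distance matrix,
# random forest with all features available at every split, and
# L1-regularized logistic regression; plus cross-partition importance
# aggregation.

new_fit_result <- function(predictions, model, importance = NULL,
                           partition = NULL) {
  stopifnot(all(predictions %in% c(0L, 1L)), !is.null(names(predictions)))
  if (!is.null(importance)) stopifnot(all(importance >= -1e-12))
  structure(list(predictions = predictions, importance = importance,
                 model = model, partition = partition),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: %d test predictions (%.1f%% positive)\n",
              x$model, length(x$predictions), 100 * mean(x$predictions)))
  invisible(x)
}

#' Nearest-neighbor prediction
#'
#' Each test strain receives the label of its minimum-distance training
#' strain. Ties are broken by the lexicographically smallest training ID,
#' making the classifier deterministic. A test strain at distance 0 from a
#' training strain (including itself, in diagnostic use) inherits that
#' strain's label.
#'
#' @param dist a [distance_matrix()] covering all train and test strains.
#' @param train_ids,test_ids strain identifiers.
#' @param train_labels named or positionally aligned 0/1 labels for
#'   `train_ids`.
#' @return a `fit_result`.
#' @export
nn_predict <- function(dist, train_ids, train_labels, test_ids) {
  if (!length(train_ids)) stop("empty training set")
  stopifnot(all(train_labels %in% c(0, 1)),
            length(train_labels) == length(train_ids))
  miss <- setdiff(c(train_ids, test_ids), rownames(dist))
  if (length(miss))
    stop("strains absent from distance matrix: ", paste(miss, collapse = ", "))
  ord <- order(train_ids)
  train_ids <- train_ids[ord]
  train_labels <- as.integer(train_labels)[ord]
  sub <- unclass(dist)[test_ids, train_ids, drop = FALSE]
  nn <- apply(sub, 1, which.min)   # first minimum = smallest ID (sorted)
  preds <- train_labels[nn]
  names(preds) <- test_ids
  new_fit_result(preds, "nn")
}

#' Random forest fit and prediction
#'
#' An ensemble of classification trees in which, by default, every tree may
#' consider all features at every split (no per-split feature subsampling):
#' with few informative genes among thousands, subsampling can omit the key
#' predictors from individual trees. Prediction is the majority vote over
#' trees; an exact 50/50 vote resolves to 0. Per-gene importances are mean
#' impurity decreases, normalized to sum to 1.
#'
#' @param X_train,X_test binary matrices (strains x genes) with dimnames.
#' @param y_train 0/1 labels for the training rows.
#' @param config list of hyperparameters: `num_trees` (default 100), `mtry`
#'   (default `NULL` = all features), `max_depth` (default `NULL` =
#'   unlimited).
#' @param seed RNG seed; fixed seed gives identical forests.
#' @return a `fit_result` with importance scores.
#' @export
rf_fit_predict <- function(X_train, y_train, X_test, config = list(),
                           seed = NULL) {
  y_train <- as.integer(y_train)
  stopifnot(all(y_train %in% c(0, 1)), nrow(X_train) == length(y_train))
  if (length(unique(y_train)) < 2)
    stop("training labels are single-class; classification undefined")
  num_trees <- config$num_trees %||% 100L
  mtry <- config$mtry %||% ncol(X_train)
  max_depth <- config$max_depth %||% 0L  # 0 = unlimited in ranger
  df_train <- data.frame(..y = factor(y_train, levels = c(0, 1)),
                         X_train, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = "..y", data = df_train,
    num.trees = num_trees, mtry = mtry, max.depth = max_depth,
    importance = "impurity", num.threads = 1L,
    seed = if (is.null(seed)) with_seed(NULL, sample.int(2^31 - 1, 1)) else seed)
  pr <- predict(fit, data = as.data.frame(X_test, check.names = FALSE),
                predict.all = TRUE, num.threads = 1L)
  votes <- pr$predictions  # n_test x num_trees of class indices (1/2)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(X_test))
  frac1 <- rowMeans(votes == 2L)
  preds <- as.integer(frac1 > 0.5)   # exact tie -> 0
  names(preds) <- rownames(X_test)
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp <- imp[colnames(X_train)]
  names(imp) <- colnames(X_train)
  new_fit_result(preds, "rf", importance = imp)
}

#' L1-regularized logistic regression fit and prediction
#'
#' Sparse linear classifier; the penalty is parameterized by
#' `penalty_strength` (the inverse-regularization constant C), mapped to a
#' lasso penalty of `1 / (C * n_train)` on the mean log-likelihood so that
#' C = 1 matches the conventional unit inverse-regularization default.
#' Predictions threshold the fitted probability at 0.5 (a probability of
#' exactly 0.5 resolves to 0).
#'
#' @inheritParams rf_fit_predict
#' @param penalty_strength inverse regularization strength C > 0; default 1.
#' @return a `fit_result`; importances are normalized absolute
#'   coefficients.
#' @export
logreg_l1_fit_predict <- function(X_train, y_train, X_test,
                                  penalty_strength = 1) {
  y_train <- as.integer(y_train)
  stopifnot(all(y_train %in% c(0, 1)), penalty_strength > 0)
  if (length(unique(y_train)) < 2)
    stop("training labels are single-class; classification undefined")
  lambda <- 1 / (penalty_strength * length(y_train))
  fit <- glmnet::glmnet(x = as.matrix(X_train), y = y_train,
                        family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE)
  p <- predict(fit, newx = as.matrix(X_test), type = "response")[, 1]
  preds <- as.integer(p > 0.5)
  names(preds) <- rownames(X_test)
  beta <- abs(as.numeric(coef(fit))[-1])
  if (sum(beta) > 0) beta <- beta / sum(beta)
  names(beta) <- colnames(X_train)
  new_fit_result(preds, "logreg_l1", importance = beta)
}

#' Aggregate feature importances across partitions
#'
#' Arithmetic mean of the per-gene importance scores over a list of fit
#' results sharing the same gene universe (e.g. 100 forests trained on 100
#' out-of-clade partitions).
#'
#' @param fit_results non-empty list of `fit_result`s with importances.
#' @return an `importance_profile`: list with `gene_ids`, `mean_importance`
#'   and `n_partitions`.
#' @export
aggregate_importance <- function(fit_results) {
  if (!length(fit_results)) stop("empty fit-result list")
  imps <- lapply(fit_results, function(f) f$importance)
  if (any(vapply(imps, is.null, logical(1))))
    stop("all fit results must carry importance scores")
  genes <- names(imps[[1]])
  ok <- vapply(imps, function(v) identical(names(v), genes), logical(1))
  if (!all(ok)) stop("fit results disagree on gene IDs")
  m <- do.call(rbind, imps)
  structure(list(gene_ids = genes, mean_importance = colMeans(m),
                 n_partitions = length(fit_results)),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, n = 5, ...) {
  cat(sprintf("Importance profile over %d partitions; top genes:\n",
              x$n_partitions))
  top <- sort(x$mean_importance, decreasing = TRUE)[seq_len(min(n, length(x$gene_ids)))]
  print(round(top, 4))
  invisible(x)
}
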