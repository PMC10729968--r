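# Null models, accuracy metrics, and the significance protocol: permutation
# t-tests against two nulls with step-down Sidak multiple-testing
# correction across traits.

#' Bernoulli null predictions
#'
#' Predicts 1 with probability p and 0 with probability 1-p, where p is the
#' fraction of 1s in the training labels: the baseline of guessing by
#' chance at the training class frequency.
#'
#' @param train_labels 0/1 training labels.
#' @param n_test number of predictions to draw.
#' @param seed RNG seed.
#' @return integer vector of 0/1 predictions.
#' @export
bernoulli_null_predict <- function(train_labels, n_test, seed = NULL) {
  stopifnot(length(train_labels) >= 1, all(train_labels %in% c(0, 1)))
  p <- mean(train_labels == 1)
  with_seed(seed, rbinom(n_test, 1L, p))
}

#' Identity (majority-class) null predictions
#'
#' Always predicts the more common training phenotype: the baseline reached
#' by overly specific or overly sensitive models. An exact tie predicts 1.
#'
#' @inheritParams bernoulli_null_predict
#' @return integer vector of 0/1 predictions.
#' @export
identity_null_predict <- function(train_labels, n_test) {
  stopifnot(length(train_labels) >= 1, all(train_labels %in% c(0, 1)))
  maj <- as.integer(mean(train_labels == 1) >= 0.5)
  rep(maj, n_test)
}

#' Accuracy and balanced accuracy
#'
#' Accuracy is the fraction of correct predictions. Balanced accuracy is
#' the arithmetic mean of sensitivity and specificity; when the labels
#' contain only one class it is undefined and reported as `NA` with
#' `balanced_defined = FALSE` (plain accuracy is still returned).
#'
#' @param predictions,labels equal-length 0/1 vectors.
#' @return list with `accuracy`, `balanced_accuracy`, `balanced_defined`.
#' @export
score <- function(predictions, labels) {
  if (!length(labels)) stop("empty input")
  stopifnot(length(predictions) == length(labels),
            all(labels %in% c(0, 1)), all(predictions %in% c(0, 1)))
  acc <- mean(predictions == labels)
  pos <- labels == 1
  if (!any(pos) || all(pos)) {
    return(list(accuracy = acc, balanced_accuracy = NA_real_,
                balanced_defined = FALSE))
  }
  sens <- mean(predictions[pos] == 1)
  spec <- mean(predictions[!pos] == 0)
  list(accuracy = acc, balanced_accuracy = (sens + spec) / 2,
       balanced_defined = TRUE)
}

pooled_t_stat <- function(sum1, sumsq1, n1, sum2, sumsq2, n2) {
  m1 <- sum1 / n1
  m2 <- sum2 / n2
  ss1 <- sumsq1 - n1 * m1^2
  ss2 <- sumsq2 - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(pmax(sp2, 0) * (1 / n1 + 1 / n2))
  d <- m1 - m2
  t <- ifelse(se > 0, d / se, ifelse(abs(d) > 0, Inf * sign(d), 0))
  t
}

#' Two-sided permutation t-test
#'
#' Permutation distribution of the pooled-variance t statistic under random
#' reassignment of the pooled values to the two groups. When the number of
#' distinct group assignments is at most `n_permutations` the distribution
#' is enumerated exactly (the observed assignment counts as one of them);
#' otherwise `n_permutations` Monte-Carlo assignments are drawn and the
#' estimate `(1 + #more extreme) / (1 + B)` is returned, which is exactly
#' uniform under a continuous null. Zero variance in the pooled data (all
#' values identical) returns p = 1.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param n_permutations Monte-Carlo budget / enumeration cap; default 1e5.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return two-sided p-value in (0, 1].
#' @export
permutation_t_test <- function(sample_a, sample_b, n_permutations = 1e5,
                               seed = NULL) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2,
            n_permutations >= 1)
  n1 <- length(sample_a); n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  if (var(pooled) == 0) return(1)
  sumsq <- pooled^2
  t_obs <- abs(pooled_t_stat(sum(sample_a), sum(sample_a^2), n1,
                             sum(sample_b), sum(sample_b^2), n2))
  n <- n1 + n2
  tot_s <- sum(pooled); tot_ss <- sum(sumsq)
  stat_for <- function(idx_mat) {
    s1 <- colSums(matrix(pooled[idx_mat], nrow = n1))
    ss1 <- colSums(matrix(sumsq[idx_mat], nrow = n1))
    abs(pooled_t_stat(s1, ss1, n1, tot_s - s1, tot_ss - ss1, n2))
  }
  n_comb <- choose(n, n1)
  tol <- 1e-12 * max(1, t_obs[is.finite(t_obs)], na.rm = TRUE)
  if (is.finite(n_comb) && n_comb <= n_permutations) {
    idx <- combn(n, n1)
    tstats <- stat_for(idx)
    mean(tstats >= t_obs - tol)
  } else {
    B <- as.integer(n_permutations)
    idx <- with_seed(seed,
      vapply(seq_len(B), function(i) sample.int(n, n1), integer(n1)))
    tstats <- stat_for(idx)
    (1 + sum(tstats >= t_obs - tol)) / (1 + B)
  }
}

#' Holm–Šidák step-down correction
#'
#' Sorts the p-values ascending, adjusts the i-th smallest of m as
#' `1 - (1 - p_(i))^(m - i + 1)`, enforces monotone non-decrease, and
#' returns the adjusted values in the original order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
holm_sidak <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  ord <- order(p_values)
  ps <- p_values[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Compare a model's accuracy distribution to both null models
#'
#' Runs two-sided permutation t-tests of the model's per-partition accuracy
#' distribution against the Bernoulli-null and identity-null distributions
#' obtained on the same partitions. "Significantly higher" is enforced as
#' the conjunction of (corrected) significance and a higher mean than both
#' nulls, since the permutation test itself is two-sided. When the model is
#' evaluated alongside other traits, pass `n_traits` so the Šidák exponent
#' reflects the whole family (joint step-down correction across traits is
#' available via [holm_sidak()] on the collected raw p-values, as done by
#' [run_benchmark()]).
#'
#' @param model_acc,bern_acc,ident_acc equal-length numeric vectors of
#'   per-partition accuracies.
#' @param alpha significance level; default 0.05.
#' @param n_permutations permutation budget for each test; default 1e5.
#' @param n_traits size of the multiple-testing family; default 1 (no
#'   correction).
#' @param seed RNG seed.
#' @return list with raw and adjusted p-values per null, the three mean
#'   accuracies, and the `significant` flag.
#' @export
compare_to_nulls <- function(model_acc, bern_acc, ident_acc, alpha = 0.05,
                             n_permutations = 1e5, n_traits = 1,
                             seed = NULL) {
  if (length(model_acc) != length(bern_acc) ||
      length(model_acc) != length(ident_acc))
    stop("mismatched partition counts between model and nulls")
  seeds <- derive_seeds(seed %||% 0L, 2)
  p_bern <- permutation_t_test(model_acc, bern_acc, n_permutations,
                               seed = if (is.null(seed)) NULL else seeds[1])
  p_ident <- permutation_t_test(model_acc, ident_acc, n_permutations,
                                seed = if (is.null(seed)) NULL else seeds[2])
  adj <- function(p) min(1, 1 - (1 - p)^n_traits)
  p_bern_adj <- adj(p_bern)
  p_ident_adj <- adj(p_ident)
  means <- c(model = mean(model_acc), bernoulli = mean(bern_acc),
             identity = mean(ident_acc))
  sig <- p_bern_adj < alpha && p_ident_adj < alpha &&
    means["model"] > means["bernoulli"] && means["model"] > means["identity"]
  list(p_bernoulli = p_bern, p_identity = p_ident,
       p_bernoulli_adj = p_bern_adj, p_identity_adj = p_ident_adj,
       means = means, significant = unname(sig))
}

#' Tail p-value of a fixed prediction against a null accuracy distribution
#'
#' For an externally supplied prediction (e.g. a constraint-based model's
#' growth predictions) with a single observed accuracy, builds the
#' distribution of null-model accuracies over many random train/test
#' partitions of the trait and returns the fraction of null accuracies
#' strictly greater than the observed one. A precomputed null distribution
#' can be supplied via `null_accuracies`, bypassing generation.
#'
#' @param observed_accuracy observed accuracy in \[0, 1\].
#' @param trait_labels named 0/1 vector of the trait over all strains (used
#'   to generate partitions unless `null_accuracies` is given).
#' @param null_kind `"bernoulli"` or `"identity"`.
#' @param n_partitions number of random partitions; default 1e5.
#' @param test_fraction held-out fraction per partition; default 0.2.
#' @param seed RNG seed.
#' @param null_accuracies optional numeric vector of precomputed null
#'   accuracies.
#' @param add_one small-sample guard: if `TRUE`, returns
#'   `(1 + count) / (1 + total)`; default `FALSE` (strict ratio).
#' @return p-value in \[0, 1\].
#' @export
fixed_prediction_pvalue <- function(observed_accuracy, trait_labels = NULL,
                                    null_kind = c("bernoulli", "identity"),
                                    n_partitions = 1e5, test_fraction = 0.2,
                                    seed = NULL, null_accuracies = NULL,
                                    add_one = FALSE) {
  stopifnot(observed_accuracy >= 0, observed_accuracy <= 1)
  null_kind <- match.arg(null_kind)
  if (is.null(null_accuracies)) {
    stopifnot(!is.null(trait_labels), n_partitions >= 1)
    y <- as.integer(trait_labels)
    n <- length(y)
    k <- min(n - 1L, max(1L, round(test_fraction * n)))
    B <- as.integer(n_partitions)
    null_accuracies <- with_seed(seed, {
      test_idx <- vapply(seq_len(B), function(i) sample.int(n, k),
                         integer(k))
      test_lab <- matrix(y[test_idx], nrow = k)
      ones_test <- colSums(test_lab)
      train_ones <- sum(y) - ones_test
      n_train <- n - k
      if (null_kind == "identity") {
        maj <- as.integer(train_ones / n_train >= 0.5)
        colMeans(test_lab == rep(maj, each = k))
      } else {
        p <- train_ones / n_train
        preds <- matrix(rbinom(k * B, 1L, rep(p, each = k)), nrow = k)
        colMeans(preds == test_lab)
      }
    })
  }
  cnt <- sum(null_accuracies > observed_accuracy)
  tot <- length(null_accuracies)
  if (add_one) (1 + cnt) / (1 + tot) else cnt / tot
}
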