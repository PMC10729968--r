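# Phylogeny-trait correlation: the mean trait-difference curve, the
# sliding-window chi-square correlation length, and the nearest-neighbor
# mimicry (mu) diagnostic for classifiers.

pairwise_upper <- function(dist, trait) {
  ids <- rownames(dist)
  trait <- trait[ids]
  idx <- which(upper.tri(dist), arr.ind = TRUE)
  list(d = unclass(dist)[idx],
       diff = abs(trait[idx[, 1]] - trait[idx[, 2]]))
}

#' Mean trait difference as a function of phylogenetic distance
#'
#' For each distance d in the grid, the mean of |y_a - y_b| over all strain
#' pairs at distance <= d, together with a null band obtained by shuffling
#' the trait labels: the null mean and its standard deviation over
#' `n_bootstrap` shuffles. A rising curve that leaves the null band only
#' beyond some distance indicates phylogenetic conservation of the trait up
#' to that distance.
#'
#' @param dist a [distance_matrix()].
#' @param trait named 0/1 vector over the strains of `dist`.
#' @param d_grid distances at which to evaluate; default 30 equal steps up
#'   to the maximum pairwise distance.
#' @param n_bootstrap number of label shuffles for the null band; default
#'   100.
#' @param seed RNG seed.
#' @return data.frame with columns `d`, `mean_diff` (NA where no pair lies
#'   below d), `null_mean`, `null_sd`.
#' @export
trait_difference_curve <- function(dist, trait, d_grid = NULL,
                                   n_bootstrap = 100, seed = NULL) {
  stopifnot(inherits(dist, "dist_matrix"), n_bootstrap >= 1)
  pw <- pairwise_upper(dist, trait)
  if (is.null(d_grid))
    d_grid <- seq(0, max(pw$d), length.out = 31)[-1]
  curve_of <- function(diffs) {
    vapply(d_grid, function(d) {
      sel <- pw$d <= d
      if (!any(sel)) NA_real_ else mean(diffs[sel])
    }, numeric(1))
  }
  obs <- curve_of(pw$diff)
  ids <- rownames(dist)
  y <- unname(trait[ids])
  idx <- which(upper.tri(dist), arr.ind = TRUE)
  boots <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      ys <- sample(y)
      curve_of(abs(ys[idx[, 1]] - ys[idx[, 2]]))
    }, numeric(length(d_grid)))
  })
  boots <- matrix(boots, nrow = length(d_grid))
  data.frame(d = d_grid, mean_diff = obs,
             null_mean = rowMeans(boots, na.rm = TRUE),
             null_sd = apply(boots, 1, sd, na.rm = TRUE))
}

#' Phylogeny-trait correlation length
#'
#' Slides a distance window `[d - window_width, d)` along the pairwise
#' distance axis. For each window position it builds the 2x2 contingency
#' table counting strain pairs inside vs outside the window against
#' same-trait vs different-trait, and computes a Pearson chi-square test.
#' A window counts as significant when its p-value falls below `alpha`
#' *and* it shows an excess of same-trait pairs inside the window (so
#' anti-correlation cannot set the length). Correlation is detected only
#' when the smallest-d window is itself significant; the correlation
#' length is then the largest significant d, and 0 otherwise. Windows with
#' an empty row or column are skipped as non-significant.
#'
#' @inheritParams trait_difference_curve
#' @param window_width width of the sliding window (tree-distance units);
#'   default 0.1.
#' @param d_grid window endpoints; default from `window_width` to the
#'   maximum pairwise distance in steps of `window_width / 2`.
#' @param alpha per-window significance level; default 0.05.
#' @param correct use the continuity correction in the 2x2 chi-square test;
#'   default TRUE.
#' @return object of class `correlation_length_result`: list with
#'   `correlation_length` and a per-window data.frame `windows`
#'   (`d`, `chisq`, `p_value`, `same_excess`, `significant`).
#' @export
correlation_length <- function(dist, trait, window_width = 0.1,
                               d_grid = NULL, alpha = 0.05,
                               correct = TRUE) {
  stopifnot(inherits(dist, "dist_matrix"), window_width > 0,
            alpha > 0, alpha < 1)
  pw <- pairwise_upper(dist, trait)
  same <- pw$diff == 0
  if (is.null(d_grid)) {
    dmax <- max(pw$d)
    d_grid <- seq(window_width, dmax + window_width / 2,
                  by = window_width / 2)
  }
  rows <- lapply(d_grid, function(d) {
    inside <- pw$d >= (d - window_width) & pw$d < d
    tab <- rbind(inside = c(same = sum(inside & same),
                            diff = sum(inside & !same)),
                 outside = c(same = sum(!inside & same),
                             diff = sum(!inside & !same)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(data.frame(d = d, chisq = NA_real_, p_value = NA_real_,
                        same_excess = NA, significant = FALSE))
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    excess <- tab[1, 1] / sum(tab[1, ]) > tab[2, 1] / sum(tab[2, ])
    data.frame(d = d, chisq = unname(ct$statistic),
               p_value = unname(ct$p.value), same_excess = excess,
               significant = ct$p.value < alpha && excess)
  })
  windows <- do.call(rbind, rows)
  # correlation is "detected" only when the smallest-d window is itself
  # significant; the length is then the largest significant d
  len <- if (isTRUE(windows$significant[1]))
    max(windows$d[windows$significant]) else 0
  structure(list(correlation_length = len, windows = windows,
                 window_width = window_width, alpha = alpha),
            class = "correlation_length_result")
}

#' @export
print.correlation_length_result <- function(x, ...) {
  cat(sprintf("Phylogeny-trait correlation length: %.4g (%d/%d windows significant)\n",
              x$correlation_length, sum(x$windows$significant),
              nrow(x$windows)))
  invisible(x)
}

#' Nearest-neighbor mimicry diagnostic
#'
#' Asks whether a trained classifier f behaves like a 1-nearest-neighbor
#' classifier on L1 genotype distance. For each partition i:
#' `mu_i = mean over test strains of |f(x_test) - f(x_nn)|`, where x_nn is
#' the test strain's L1-nearest training genotype; `mu_rand_i` replaces the
#' nearest neighbor by a uniformly drawn training strain. If f were exactly
#' 1-NN on L1, mu_i = 0 in every partition. The two distributions are
#' compared by a permutation t-test.
#'
#' The nearest-neighbor lookup always uses the L1 genotype metric (with the
#' lexicographic tie-break of [nn_predict()]), regardless of the model
#' under test.
#'
#' @param model_runner function `(X_train, y_train, seed)` returning a
#'   prediction function `(X_new) -> 0/1 vector` applicable to arbitrary
#'   genotype rows. See [runner_nn()], [runner_rf()], [runner_logreg()].
#' @param genotypes a [genotype_matrix()] covering all strains.
#' @param labels named 0/1 trait vector.
#' @param partitions list of `partition` objects.
#' @param n_permutations permutation budget for the comparison; default
#'   1e5.
#' @param seed RNG seed (model fits, random-strain draws, final test).
#' @return object of class `mimicry_result`: list with `mu`, `mu_rand`
#'   (per-partition), and `p_value`.
#' @export
nn_mimicry <- function(model_runner, genotypes, labels, partitions,
                       n_permutations = 1e5, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"), length(partitions) >= 1)
  dist <- distance_matrix(genotypes, "l1")
  seeds <- derive_seeds(seed %||% 0L, length(partitions) + 1L)
  res <- lapply(seq_along(partitions), function(i) {
    part <- partitions[[i]]
    if (!length(part$test_ids)) stop("empty test set in partition")
    tr <- sort(part$train_ids)
    te <- part$test_ids
    f <- model_runner(genotypes[tr, , drop = FALSE], labels[tr], seeds[i])
    sub <- unclass(dist)[te, tr, drop = FALSE]
    nn_ids <- tr[apply(sub, 1, which.min)]
    rand_ids <- with_seed(seeds[i] + 1L,
                          sample(tr, length(te), replace = TRUE))
    f_test <- f(genotypes[te, , drop = FALSE])
    f_nn <- f(genotypes[nn_ids, , drop = FALSE])
    f_rand <- f(genotypes[rand_ids, , drop = FALSE])
    c(mu = mean(abs(f_test - f_nn)), mu_rand = mean(abs(f_test - f_rand)))
  })
  mu <- vapply(res, `[[`, numeric(1), "mu")
  mu_rand <- vapply(res, `[[`, numeric(1), "mu_rand")
  p <- if (length(mu) >= 2)
    permutation_t_test(mu, mu_rand, n_permutations,
                       seed = seeds[length(seeds)])
  else NA_real_
  structure(list(mu = mu, mu_rand = mu_rand, p_value = p),
            class = "mimicry_result")
}

#' @export
print.mimicry_result <- function(x, ...) {
  cat(sprintf("NN-mimicry: mean mu = %.4f, mean mu_rand = %.4f, p = %.4g\n",
              mean(x$mu), mean(x$mu_rand), x$p_value))
  invisible(x)
}

#' Model runners for [nn_mimicry()]
#'
#' Each returns a closure fitting the classifier on the given training data
#' and predicting 0/1 for arbitrary genotype rows.
#'
#' @param config hyperparameter list for the random forest (see
#'   [rf_fit_predict()]).
#' @param penalty_strength inverse regularization C for the logistic
#'   runner.
#' @return a function `(X_train, y_train, seed) -> (X_new -> 0/1 vector)`.
#' @export
runner_nn <- function() {
  function(X_train, y_train, seed = NULL) {
    X_train <- unclass(X_train)
    ord <- order(rownames(X_train))
    X_train <- X_train[ord, , drop = FALSE]
    y_train <- as.integer(y_train)[ord]
    function(X_new) {
      X_new <- unclass(X_new)
      apply(X_new, 1, function(x) {
        d <- colSums(abs(t(X_train) - x))
        y_train[which.min(d)]
      })
    }
  }
}

#' @rdname runner_nn
#' @export
runner_rf <- function(config = list()) {
  function(X_train, y_train, seed = NULL) {
    function(X_new) {
      fr <- rf_fit_predict(X_train, y_train, X_new, config = config,
                           seed = seed)
      unname(fr$predictions)
    }
  }
}

#' @rdname runner_nn
#' @export
runner_logreg <- function(penalty_strength = 1) {
  function(X_train, y_train, seed = NULL) {
    function(X_new) {
      unname(logreg_l1_fit_predict(X_train, y_train, X_new,
                                   penalty_strength)$predictions)
    }
  }
}
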