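test_that("trait-difference curve matches direct pair enumeration", {
  # two 3-leaf clades with opposite traits, separated by a long branch
  txt <- "((a:0.1,(b:0.1,c:0.1):0.05):1,(d:0.1,(e:0.1,f:0.1):0.05):1);"
  tree <- ape::read.tree(text = txt)
  d <- distance_matrix(tree)
  y <- c(a = 1, b = 1, c = 1, d = 0, e = 0, f = 0)
  curve <- trait_difference_curve(d, y, d_grid = c(0.5, 3), n_bootstrap = 5,
                                  seed = 1)
  # below 0.5: only within-clade pairs -> all same trait
  expect_equal(curve$mean_diff[1], 0)
  # at 3: all 15 pairs, 9 cross-clade differ
  expect_equal(curve$mean_diff[2], 9 / 15)

  # constant trait: curve identically 0
  c0 <- trait_difference_curve(d, c(a = 1, b = 1, c = 1, d = 1, e = 1,
                                    f = 1),
                               d_grid = c(0.5, 3), n_bootstrap = 3, seed = 1)
  expect_equal(c0$mean_diff, c(0, 0))

  # curve bounded in [0, 1]
  expect_true(all(curve$mean_diff >= 0 & curve$mean_diff <= 1))
})

test_that("random balanced traits plateau near 2p(1-p)", {
  set.seed(12)
  tree <- simulate_tree(60, seed = 17)
  d <- distance_matrix(tree)
  y <- sample(rep(0:1, 30))
  names(y) <- tree$tip.label
  curve <- trait_difference_curve(d, y, n_bootstrap = 10, seed = 2)
  expect_equal(curve$mean_diff[nrow(curve)], 0.5, tolerance = 0.1)
})

test_that("correlation length detects clade-bound traits and not shuffles", {
  set.seed(13)
  # trait = membership of one deep clade; within-clade distances are small
  # compared to the inter-clade distance
  txt <- "((a:0.05,(b:0.05,c:0.05):0.02):2,((d:0.05,e:0.05):0.02,(f:0.05,g:0.05):0.02):2);"
  tree <- ape::read.tree(text = txt)
  d <- distance_matrix(tree)
  y <- c(a = 1, b = 1, c = 1, d = 0, e = 0, f = 0, g = 0)
  res <- correlation_length(d, y, window_width = 0.2)
  expect_gt(res$correlation_length, 0)
  # brute-force contingency oracle at the first window [0, 0.2):
  pairs <- t(combn(names(y), 2))
  dv <- unclass(d)[pairs]
  same <- y[pairs[, 1]] == y[pairs[, 2]]
  inside <- dv < 0.2
  tab <- table(inside, same)
  expect_equal(unname(res$windows$chisq[1]),
               unname(suppressWarnings(chisq.test(tab)$statistic)))

  # invariance to relabeling 0 <-> 1
  res_flip <- correlation_length(d, 1 - y, window_width = 0.2)
  expect_equal(res_flip$correlation_length, res$correlation_length)

  # constant trait: all windows degenerate -> 0
  resc <- correlation_length(d, c(a = 1, b = 1, c = 1, d = 1, e = 1, f = 1,
                                  g = 1),
                             window_width = 0.2)
  expect_equal(resc$correlation_length, 0)
})

test_that("type-I error of the correlation length is controlled on shuffles", {
  set.seed(14)
  tree <- simulate_tree(48, seed = 23)
  d <- distance_matrix(tree)
  hits <- replicate(40, {
    y <- sample(rep(0:1, 24))
    names(y) <- tree$tip.label
    correlation_length(d, y, window_width = max(d) / 4)$correlation_length > 0
  })
  expect_lte(mean(hits), 0.2)
})

test_that("the mu diagnostic is exactly zero for the 1-NN classifier itself", {
  set.seed(15)
  tree <- simulate_tree(40, seed = 31)
  G <- simulate_gene_content(tree, 60, seed = 32)
  y <- unclass(G)[, 1]; names(y) <- rownames(G)
  parts <- lapply(1:5, function(i)
    random_partition(rownames(G), 0.2, seed = i))
  res <- nn_mimicry(runner_nn(), G, y, parts, n_permutations = 200,
                    seed = 3)
  expect_equal(res$mu, rep(0, 5))
})

test_that("constant and coin-flip classifiers give the expected mu values", {
  set.seed(16)
  tree <- simulate_tree(40, seed = 33)
  G <- simulate_gene_content(tree, 30, seed = 34)
  y <- unclass(G)[, 1]; names(y) <- rownames(G)
  parts <- lapply(1:4, function(i)
    random_partition(rownames(G), 0.25, seed = 10 + i))

  constant_runner <- function(X_train, y_train, seed = NULL) {
    function(X_new) rep(1L, nrow(X_new))
  }
  res <- nn_mimicry(constant_runner, G, y, parts, n_permutations = 200,
                    seed = 4)
  expect_equal(res$mu, rep(0, 4))
  expect_equal(res$mu_rand, rep(0, 4))

  # classifier flipping an i.i.d. fair coin per input: E[mu] = 0.5
  coin_runner <- function(X_train, y_train, seed = NULL) {
    function(X_new) sample(0:1, nrow(X_new), replace = TRUE)
  }
  parts_many <- lapply(1:60, function(i)
    random_partition(rownames(G), 0.25, seed = 100 + i))
  res2 <- nn_mimicry(coin_runner, G, y, parts_many, n_permutations = 200,
                     seed = 5)
  expect_lt(abs(mean(res2$mu) - 0.5), 0.06)
  expect_lt(abs(mean(res2$mu_rand) - 0.5), 0.06)
})

test_that("random forests mimic the 1-NN more than a random-strain baseline", {
  set.seed(17)
  tree <- simulate_tree(60, seed = 35)
  G <- simulate_gene_content(tree, 80, seed = 36)
  lt <- random_logic_trait(colnames(G), 3, seed = 39)  # balanced trait
  y <- evaluate_logic_trait(lt, G)
  expect_true(mean(y) >= 0.1 && mean(y) <= 0.9)
  parts <- lapply(1:8, function(i)
    random_partition(rownames(G), 0.2, seed = 200 + i))
  res <- nn_mimicry(runner_rf(), G, y, parts, n_permutations = 1000,
                    seed = 6)
  expect_lte(mean(res$mu), mean(res$mu_rand))
})
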