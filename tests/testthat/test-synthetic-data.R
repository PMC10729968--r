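test_that("simulated trees are bifurcating, sized correctly and reproducible", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(t2$Nnode, 1)

  t64 <- simulate_tree(64, seed = 2)
  expect_equal(length(t64$tip.label), 64)
  expect_equal(t64$Nnode, 63)          # 2n - 1 nodes total
  expect_true(ape::is.binary(t64))
  expect_true(ape::is.rooted(t64))
  expect_true(all(t64$edge.length >= 0))

  expect_identical(ape::write.tree(simulate_tree(20, seed = 5)),
                   ape::write.tree(simulate_tree(20, seed = 5)))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("gene content follows the two-state gain/loss dynamics", {
  tree <- simulate_tree(100, seed = 3)
  # loss -> 0 with root present: gene fixed at presence
  G1 <- simulate_gene_content(tree, 200, gain_rate = 50, loss_rate = 1e-9,
                              seed = 4)
  expect_gt(mean(G1), 0.999)

  # gain = loss: stationary frequency 1/2 across many genes
  G2 <- simulate_gene_content(tree, 2000, gain_rate = 1, loss_rate = 1,
                              seed = 5)
  expect_equal(mean(G2), 0.5, tolerance = 0.03)
})

test_that("leaf-pair same-state frequency matches the closed form", {
  # cherry with controllable patristic distance
  for (t_half in c(0.2, 1)) {
    tree <- ape::read.tree(
      text = sprintf("(A:%f,B:%f);", t_half, t_half))
    n_genes <- 4000
    G <- simulate_gene_content(tree, n_genes, gain_rate = 0.6,
                               loss_rate = 1.4, seed = 6)
    p_hat <- mean(unclass(G)["A", ] == unclass(G)["B", ])
    p_exp <- pair_same_state_prob(2 * t_half, 0.6, 1.4)
    se <- sqrt(p_exp * (1 - p_exp) / n_genes)
    expect_lt(abs(p_hat - p_exp), 3 * se)
  }
})

test_that("leaf-pair correlation decays with patristic distance", {
  tree <- simulate_tree(40, seed = 7)
  G <- simulate_gene_content(tree, 1500, seed = 8)
  d <- distance_matrix(tree)
  pairs <- t(combn(rownames(G), 2))
  same <- vapply(seq_len(nrow(pairs)), function(i)
    mean(unclass(G)[pairs[i, 1], ] == unclass(G)[pairs[i, 2], ]),
    numeric(1))
  dv <- unclass(d)[pairs]
  near <- same[dv <= stats::median(dv)]
  far <- same[dv > stats::median(dv)]
  expect_gt(mean(near), mean(far))
})

test_that("logic traits honor the modularity constraint", {
  # single gene: trait is that gene
  lt1 <- random_logic_trait(paste0("g", 1:5), 1, seed = 9)
  expect_equal(lt1$expression, lt1$gene_ids)

  count_leaves <- function(e) {
    if (is.character(e)) return(1L)
    count_leaves(e$left) + count_leaves(e$right)
  }
  check_mod <- function(e, mod) {
    if (is.character(e)) return(TRUE)
    l <- count_leaves(e$left); r <- count_leaves(e$right)
    min(l, r) / (l + r) >= mod && check_mod(e$left, mod) &&
      check_mod(e$right, mod)
  }
  # modularity 0.5 on 4 genes forces a 2|2 then 1|1 split
  for (s in 1:10) {
    lt <- random_logic_trait(paste0("g", 1:8), 4, modularity = 0.5,
                             seed = s)
    expect_equal(count_leaves(lt$expression$left), 2L)
    expect_true(check_mod(lt$expression, 0.5))
  }
  for (s in 1:10) {
    lt <- random_logic_trait(paste0("g", 1:20), 7, modularity = 0.3,
                             seed = s)
    expect_true(check_mod(lt$expression, 0.3))
  }
  # modularity 0 admits any split
  lt0 <- random_logic_trait(paste0("g", 1:6), 3, modularity = 0, seed = 1)
  expect_true(check_mod(lt0$expression, 0))
  # infeasible: 3 genes cannot split with ratio >= 0.4
  expect_error(random_logic_trait(paste0("g", 1:5), 3, modularity = 0.4,
                                  seed = 1),
               "infeasible")
})

test_that("logic-trait evaluation matches the truth table and is monotone", {
  G <- toy_genotype(rbind(c(1, 0, 1), c(0, 0, 0), c(1, 1, 1)),
                    genes = c("g1", "g2", "g3"))
  lt <- structure(list(
    expression = list(op = "OR",
                      left = list(op = "AND", left = "g1", right = "g2"),
                      right = "g3"),
    gene_ids = c("g1", "g2", "g3"), modularity = 0),
    class = "logic_trait")
  y <- evaluate_logic_trait(lt, G)
  expect_equal(unname(y), c(1L, 0L, 1L))  # (1&0)|1, (0&0)|0, (1&1)|1

  # monotone: flipping any gene 0 -> 1 never flips trait 1 -> 0
  set.seed(25)
  for (i in 1:20) {
    lt <- random_logic_trait(paste0("g", 1:6), sample(2:5, 1),
                             seed = sample.int(1e6, 1))
    x <- rbinom(6, 1, 0.5)
    G1 <- toy_genotype(matrix(x, 1), genes = paste0("g", 1:6))
    y1 <- evaluate_logic_trait(lt, G1)
    for (j in which(x == 0)) {
      x2 <- x; x2[j] <- 1
      G2 <- toy_genotype(matrix(x2, 1), genes = paste0("g", 1:6))
      expect_gte(evaluate_logic_trait(lt, G2), y1)
    }
  }
  expect_error(
    evaluate_logic_trait(lt, toy_genotype(matrix(0, 1, 2),
                                          genes = c("g1", "g2"))),
    "absent")
})

test_that("benchmark generation respects grids, balance and determinism", {
  sets <- generate_benchmark(n_samples_grid = c(30, 50),
                             n_genes_grid = 40,
                             n_trait_genes_grid = c(2, 3),
                             n_traits = 5, seed = 10)
  expect_length(sets, 4)
  for (ds in sets) {
    expect_false(ds$infeasible %||% FALSE)
    expect_equal(ncol(ds$traits), 5)
    expect_false(anyDuplicated(rownames(ds$genotypes)) > 0)
    expect_false(anyDuplicated(colnames(ds$genotypes)) > 0)
    expect_setequal(rownames(ds$genotypes), ds$tree$tip.label)
    freqs <- colMeans(unclass(ds$traits))
    expect_true(all(freqs >= 0.1 & freqs <= 0.9))
  }
  sets2 <- generate_benchmark(n_samples_grid = c(30, 50),
                              n_genes_grid = 40,
                              n_trait_genes_grid = c(2, 3),
                              n_traits = 5, seed = 10)
  expect_identical(unclass(sets[[1]]$traits), unclass(sets2[[1]]$traits))
})
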