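# Train/test partitioning: random holdout and out-of-clade holdout, where
# the test set is one or two monophyletic subtrees of the phylogeny.

new_partition <- function(train_ids, test_ids, regime, seed,
                          clade_nodes = NULL) {
  stopifnot(length(test_ids) >= 1, length(train_ids) >= 1,
            !anyDuplicated(c(train_ids, test_ids)))
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 regime = regime, seed = seed, clade_nodes = clade_nodes),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("%s partition: %d train / %d test strains (seed %s)\n",
              x$regime, length(x$train_ids), length(x$test_ids),
              format(x$seed)))
  invisible(x)
}

#' Random train/test partition
#'
#' Holds out `round(test_fraction * n)` strains (at least 1, at most n-1),
#' sampled uniformly without replacement.
#'
#' @param strain_ids character vector of strain identifiers.
#' @param test_fraction fraction held out; default 0.20.
#' @param seed RNG seed for reproducibility.
#' @return a `partition` object with `regime = "random"`.
#' @export
random_partition <- function(strain_ids, test_fraction = 0.2, seed = NULL) {
  n <- length(strain_ids)
  if (n < 2) stop("need at least 2 strains to partition")
  stopifnot(test_fraction > 0, test_fraction < 1)
  k <- min(n - 1L, max(1L, round(test_fraction * n)))
  test <- with_seed(seed, sample(strain_ids, k))
  new_partition(setdiff(strain_ids, test), sort(test), "random", seed)
}

# Leaf sets of every node (tips and internal), as tip labels.
node_leaf_sets <- function(tree) {
  n <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(n + tree$Nnode), type = "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

#' Enumerate candidate out-of-clade test sets
#'
#' A candidate test set is either a single clade (subtree) whose leaf count
#' lies within `[ceiling(min_fraction * n), floor(max_fraction * n)]`, or an
#' unordered pair of leaf-disjoint such clades whose combined leaf count
#' lies in the same range. Single leaves count as 1-leaf clades and are
#' admitted only when the lower bound is 1.
#'
#' @param tree rooted `phylo` tree of the usable strains.
#' @param min_fraction,max_fraction target test-set size range as fractions
#'   of the leaf count; defaults 0.10 and 0.30.
#' @return list of candidates, each a list with `nodes` (1 or 2 tree node
#'   numbers) and `leaves` (tip labels).
#' @export
enumerate_clade_testsets <- function(tree, min_fraction = 0.1,
                                     max_fraction = 0.3) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (n < 4) stop("need at least 4 leaves for out-of-clade partitioning")
  stopifnot(min_fraction > 0, min_fraction < max_fraction, max_fraction < 1)
  lo <- ceiling(min_fraction * n)
  hi <- floor(max_fraction * n)
  if (lo > hi)
    stop(sprintf("empty test-size range: [%d, %d] leaves", lo, hi))
  sets <- node_leaf_sets(tree)
  sizes <- lengths(sets)
  # exclude the root (test set must not be all strains)
  root <- n + 1L
  nodes <- setdiff(which(sizes >= lo & sizes <= hi & sizes < n), root)
  singles <- lapply(nodes, function(nd)
    list(nodes = nd, leaves = sort(sets[[nd]])))
  pairs <- list()
  if (length(nodes) >= 2) {
    cmb <- combn(nodes, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      tot <- sizes[a] + sizes[b]
      if (tot < lo || tot > hi || tot >= n) next
      if (length(intersect(sets[[a]], sets[[b]])) > 0) next
      pairs[[length(pairs) + 1L]] <-
        list(nodes = c(a, b), leaves = sort(c(sets[[a]], sets[[b]])))
    }
  }
  out <- c(singles, pairs)
  if (!length(out))
    stop("no clade test set in the target size range; the tree is too unbalanced")
  out
}

#' Out-of-clade train/test partition
#'
#' Samples one candidate uniformly from [enumerate_clade_testsets()]; its
#' leaves form the test set, all remaining leaves the training set.
#'
#' @inheritParams enumerate_clade_testsets
#' @param seed RNG seed.
#' @param candidates optional precomputed candidate list (to amortize
#'   enumeration across many partitions).
#' @return a `partition` object with `regime = "out_of_clade"`.
#' @export
out_of_clade_partition <- function(tree, min_fraction = 0.1,
                                   max_fraction = 0.3, seed = NULL,
                                   candidates = NULL) {
  if (is.null(candidates))
    candidates <- enumerate_clade_testsets(tree, min_fraction, max_fraction)
  pick <- with_seed(seed, sample.int(length(candidates), 1L))
  cand <- candidates[[pick]]
  new_partition(setdiff(sort(tree$tip.label), cand$leaves), cand$leaves,
                "out_of_clade", seed, clade_nodes = cand$nodes)
}
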