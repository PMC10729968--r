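# Independent oracles and small fixture builders used across the suite.
# These deliberately use brute-force loops / closed forms, not the package's
# own code paths.

# Direct-enumeration conditional entropy: loop over unique rows, then over
# y values, summing -p log2 p terms.
entropy_oracle <- function(X, y) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  keys <- apply(X, 1, paste, collapse = "|")
  H <- 0
  for (k in unique(keys)) {
    sel <- keys == k
    pk <- sum(sel) / length(keys)
    h <- 0
    for (t in c(0, 1)) {
      pt <- mean(y[sel] == t)
      if (pt > 0) h <- h - pt * log2(pt)
    }
    H <- H + pk * h
  }
  H
}

# Closed-form step-down Sidak, written as an explicit loop.
holm_sidak_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 0
  for (i in seq_len(m)) {
    a <- 1 - (1 - p[ord[i]])^(m - i + 1)
    a <- max(a, prev)
    prev <- a
    adj[ord[i]] <- min(a, 1)
  }
  adj
}

# Tree-traversal monophyly check independent of the enumeration code.
is_clade <- function(tree, tips) {
  if (length(tips) == length(tree$tip.label)) return(TRUE)
  if (length(tips) == 1) return(TRUE)
  ape::is.monophyletic(tree, tips)
}

# A partition's test set must be 1 or 2 leaf-disjoint monophyletic groups
# covering the recorded clade nodes, in the target size range.
check_ooc_partition <- function(tree, part, min_fraction = 0.1,
                                max_fraction = 0.3) {
  n <- length(tree$tip.label)
  te <- part$test_ids
  ok <- length(intersect(part$train_ids, te)) == 0 &&
    setequal(c(part$train_ids, te), tree$tip.label) &&
    length(te) >= 1 &&
    length(te) >= ceiling(min_fraction * n) &&
    length(te) <= floor(max_fraction * n)
  if (!ok) return(FALSE)
  nodes <- part$clade_nodes
  if (!length(nodes) %in% c(1, 2)) return(FALSE)
  groups <- lapply(nodes, function(nd) {
    tips <- phangorn::Descendants(tree, nd, type = "tips")[[1]]
    tree$tip.label[tips]
  })
  if (length(groups) == 2 &&
      length(intersect(groups[[1]], groups[[2]])) > 0) return(FALSE)
  if (!setequal(unlist(groups), te)) return(FALSE)
  all(vapply(groups, function(g) is_clade(tree, g), logical(1)))
}

# Small genotype matrix with explicit values.
toy_genotype <- function(values, strains = NULL, genes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- strains %||% sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- genes %||% sprintf("g%02d", seq_len(ncol(m)))
  genotype_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Balanced XOR design: y = g1 XOR g2 with all four (g1, g2) combinations
# equally represented, plus random decoy genes.
xor_design <- function(n_rows = 64, n_decoys = 4, seed = 1) {
  set.seed(seed)
  combos <- cbind(rep(c(0, 1), each = 2), rep(c(0, 1), 2))
  idx <- rep(seq_len(4), length.out = n_rows)
  g12 <- combos[sample(idx), ]
  decoys <- matrix(rbinom(n_rows * n_decoys, 1, 0.5), n_rows)
  X <- cbind(g12, decoys)
  colnames(X) <- c("g1", "g2", sprintf("d%02d", seq_len(n_decoys)))
  rownames(X) <- sprintf("s%03d", seq_len(n_rows))
  list(X = X, y = as.integer(xor(X[, "g1"] == 1, X[, "g2"] == 1)))
}

fixture_graph <- function() {
  read_reaction_graph(system.file("extdata", "reaction_graph_synthetic.json",
                                  package = "phenoclade"))
}

fixture_graph_expected <- function() {
  jsonlite::read_json(
    system.file("extdata", "reaction_graph_synthetic_expected.json",
                package = "phenoclade"),
    simplifyVector = TRUE)
}
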