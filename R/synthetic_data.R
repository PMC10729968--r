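# Simulators: random phylogenies, gene gain/loss along the tree, boolean
# logic traits with a modularity constraint, and the benchmark-grid
# generator used for the sample-size / gene-number simulation study.

#' Simulate a random bifurcating phylogeny
#'
#' Grows the topology by sequential random leaf attachment: starting from a
#' two-leaf cherry, each further leaf is attached to a uniformly chosen
#' existing edge. Every edge then receives an independent exponential
#' branch length with mean `branch_scale`.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param branch_scale mean branch length (tree-distance units); default
#'   0.1.
#' @param seed RNG seed.
#' @return a rooted `phylo` object with leaf labels `s001, s002, ...`.
#' @export
simulate_tree <- function(n_leaves, branch_scale = 0.1, seed = NULL) {
  if (n_leaves < 2) stop("need at least 2 leaves")
  stopifnot(branch_scale > 0)
  with_seed(seed, {
    # nodes: negative = internal (root = -1), positive = leaf index
    edges <- matrix(c(-1L, 1L, -1L, 2L), ncol = 2, byrow = TRUE)
    next_int <- -2L
    for (leaf in seq_len(n_leaves)[-(1:2)]) {
      e <- sample.int(nrow(edges), 1L)
      u <- edges[e, 1]; v <- edges[e, 2]
      w <- next_int; next_int <- next_int - 1L
      edges[e, ] <- c(u, w)
      edges <- rbind(edges, c(w, v), c(w, leaf))
    }
    n_int <- n_leaves - 1L
    # ape numbering: leaves 1..n, root n+1, internals n+2.. in creation order
    remap <- function(x) ifelse(x > 0, x, n_leaves - x)  # -1 -> n+1
    edge_mat <- cbind(remap(edges[, 1]), remap(edges[, 2]))
    storage.mode(edge_mat) <- "integer"
    lens <- rexp(nrow(edge_mat), rate = 1 / branch_scale)
    tree <- structure(list(edge = edge_mat, edge.length = lens,
                           Nnode = n_int,
                           tip.label = sprintf("s%03d", seq_len(n_leaves))),
                      class = "phylo")
    tree <- ape::reorder.phylo(tree, "cladewise")
    validate_tree(tree)
    tree
  })
}

#' Simulate gene presence/absence along a phylogeny
#'
#' Each gene evolves independently as a two-state (absent/present)
#' continuous-time Markov chain along the branches, with gain rate
#' `gain_rate` (0 -> 1) and loss rate `loss_rate` (1 -> 0). The root state
#' is drawn from the stationary distribution
#' `pi = gain_rate / (gain_rate + loss_rate)`. The default rates give a
#' stationary gene frequency near 0.3 and strong phylogenetic conservation
#' at the default branch scale, comparable to real pangenomes.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param n_genes number of genes.
#' @param gain_rate,loss_rate transition rates per unit branch length;
#'   defaults 0.33 and 0.78.
#' @param seed RNG seed.
#' @return a [genotype_matrix()] of the leaf states (strains x genes).
#' @export
simulate_gene_content <- function(tree, n_genes, gain_rate = 0.33,
                                  loss_rate = 0.78, seed = NULL) {
  validate_tree(tree)
  stopifnot(gain_rate > 0, loss_rate > 0, n_genes >= 1)
  pi1 <- gain_rate / (gain_rate + loss_rate)
  rate <- gain_rate + loss_rate
  n <- length(tree$tip.label)
  with_seed(seed, {
    states <- matrix(NA_integer_, n + tree$Nnode, n_genes)
    root <- n + 1L
    states[root, ] <- rbinom(n_genes, 1L, pi1)
    ord <- rev(ape::postorder(tree))  # parents before children
    for (e in ord) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      decay <- exp(-rate * t)
      p1 <- pi1 + (states[par, ] - pi1) * decay  # P(child = 1 | parent)
      states[child, ] <- rbinom(n_genes, 1L, p1)
    }
    m <- states[seq_len(n), , drop = FALSE]
    dimnames(m) <- list(tree$tip.label,
                        sprintf("g%04d", seq_len(n_genes)))
    genotype_matrix(m)
  })
}

#' Two-leaf same-state probability under the gain/loss model
#'
#' Closed form for the probability that two leaves at patristic distance t
#' carry the same state for a gene evolving under the two-state chain at
#' stationarity: `pi^2 + (1-pi)^2 + 2 pi (1-pi) exp(-(gain+loss) t)`.
#' Used as the analytic oracle for [simulate_gene_content()].
#'
#' @param t patristic distance.
#' @param gain_rate,loss_rate transition rates.
#' @return probability of identical states.
#' @export
pair_same_state_prob <- function(t, gain_rate = 0.33, loss_rate = 0.78) {
  pi1 <- gain_rate / (gain_rate + loss_rate)
  pi1^2 + (1 - pi1)^2 + 2 * pi1 * (1 - pi1) * exp(-(gain_rate + loss_rate) * t)
}

#' Random boolean logic trait
#'
#' A trait is a binary expression tree whose leaves are distinct genes and
#' whose internal nodes are AND/OR operators drawn uniformly. The
#' `modularity` parameter (in \[0, 0.5\]) constrains every internal node's
#' split: `min(|L|, |R|) / (|L| + |R|) >= modularity`, where |.| counts the
#' genes in the left/right subtree, so higher modularity forces balanced,
#' module-like sub-expressions.
#'
#' @param gene_pool character vector of available gene IDs.
#' @param n_trait_genes number of distinct trait-defining genes.
#' @param modularity minimum split ratio; default 0.
#' @param seed RNG seed.
#' @return object of class `logic_trait`: list with `expression` (nested
#'   list with `op`/`left`/`right` or a gene ID leaf), `gene_ids`,
#'   `modularity`.
#' @export
random_logic_trait <- function(gene_pool, n_trait_genes, modularity = 0,
                               seed = NULL) {
  stopifnot(n_trait_genes >= 1, modularity >= 0, modularity <= 0.5,
            length(gene_pool) >= n_trait_genes)
  build <- function(genes) {
    m <- length(genes)
    if (m == 1L) return(genes)
    a_ok <- Filter(function(a) min(a, m - a) / m >= modularity,
                   seq_len(m - 1L))
    if (!length(a_ok))
      stop(sprintf("modularity %.2f infeasible at a %d-gene split",
                   modularity, m))
    a <- if (length(a_ok) == 1L) a_ok else sample(a_ok, 1L)
    list(op = sample(c("AND", "OR"), 1L),
         left = build(genes[seq_len(a)]),
         right = build(genes[-seq_len(a)]))
  }
  with_seed(seed, {
    genes <- sample(gene_pool, n_trait_genes)
    expr <- build(genes)
    structure(list(expression = expr, gene_ids = sort(genes),
                   modularity = modularity),
              class = "logic_trait")
  })
}

format_logic_expr <- function(e) {
  if (is.character(e)) return(e)
  sprintf("(%s %s %s)", format_logic_expr(e$left), e$op,
          format_logic_expr(e$right))
}

#' @export
print.logic_trait <- function(x, ...) {
  cat("Logic trait:", format_logic_expr(x$expression),
      sprintf("[modularity >= %.2f]\n", x$modularity))
  invisible(x)
}

#' Evaluate a logic trait on a genotype matrix
#'
#' @param trait a `logic_trait`.
#' @param genotypes a [genotype_matrix()] containing all trait genes.
#' @return named integer 0/1 vector, one value per strain.
#' @export
evaluate_logic_trait <- function(trait, genotypes) {
  stopifnot(inherits(trait, "logic_trait"))
  miss <- setdiff(trait$gene_ids, colnames(genotypes))
  if (length(miss))
    stop("trait genes absent from genotype matrix: ",
         paste(miss, collapse = ", "))
  eval_node <- function(e) {
    if (is.character(e)) return(unclass(genotypes)[, e])
    l <- eval_node(e$left); r <- eval_node(e$right)
    if (e$op == "AND") as.integer(l & r) else as.integer(l | r)
  }
  out <- eval_node(trait$expression)
  names(out) <- rownames(genotypes)
  out
}

#' Generate a grid of synthetic benchmark datasets
#'
#' Reproduces the simulation-study design: a master dataset (tree +
#' genotype matrix) is generated (or supplied), then for every combination
#' of sample size, gene number and trait-defining gene number, strains and
#' genes are subsampled without replacement and logic traits are
#' rejection-sampled until `n_traits` pass the class-balance filter (each
#' class >= `min_class_fraction` of strains), with a bounded retry budget.
#'
#' @param n_samples_grid,n_genes_grid,n_trait_genes_grid integer grids.
#' @param modularity logic-trait modularity; default 0.
#' @param n_traits traits per grid cell; default 50.
#' @param min_class_fraction minimum class fraction per trait; default
#'   0.10.
#' @param genotypes optional master [genotype_matrix()] (with `tree`); when
#'   omitted a master dataset of the maximum grid sizes is simulated.
#' @param tree master phylogeny matching `genotypes`.
#' @param branch_scale,gain_rate,loss_rate simulator parameters for the
#'   master dataset (see [simulate_tree()], [simulate_gene_content()]).
#' @param max_retries rejection-sampling budget per trait; default 1000.
#' @param seed RNG seed.
#' @return list of `synthetic_dataset` objects, one per feasible grid
#'   cell: list with `genotypes`, `tree`, `traits` (trait_table),
#'   `logic_traits`, `params`. Infeasible cells are reported with
#'   `infeasible = TRUE`.
#' @export
generate_benchmark <- function(n_samples_grid, n_genes_grid,
                               n_trait_genes_grid, modularity = 0,
                               n_traits = 50, min_class_fraction = 0.1,
                               genotypes = NULL, tree = NULL,
                               branch_scale = 0.1, gain_rate = 0.33,
                               loss_rate = 0.78, max_retries = 1000,
                               seed = NULL) {
  stopifnot(length(n_samples_grid) >= 1, length(n_genes_grid) >= 1,
            length(n_trait_genes_grid) >= 1, n_traits >= 1,
            min_class_fraction > 0, min_class_fraction < 0.5)
  seeds <- derive_seeds(seed %||% 0L, 2L)
  if (is.null(genotypes)) {
    tree <- simulate_tree(max(n_samples_grid), branch_scale,
                          seed = seeds[1])
    genotypes <- simulate_gene_content(tree, max(n_genes_grid), gain_rate,
                                       loss_rate, seed = seeds[1] + 1L)
  }
  stopifnot(inherits(tree, "phylo"),
            setequal(tree$tip.label, rownames(genotypes)),
            max(n_samples_grid) <= nrow(genotypes),
            max(n_genes_grid) <= ncol(genotypes))
  grid <- expand.grid(n_samples = n_samples_grid, n_genes = n_genes_grid,
                      n_trait_genes = n_trait_genes_grid)
  cell_seeds <- derive_seeds(seeds[2], nrow(grid))
  out <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    ns <- grid$n_samples[ci]; ng <- grid$n_genes[ci]
    ntg <- grid$n_trait_genes[ci]
    out[[ci]] <- with_seed(cell_seeds[ci], {
      strains <- sort(sample(rownames(genotypes), ns))
      genes <- sort(sample(colnames(genotypes), ng))
      sub <- genotype_matrix(unclass(genotypes)[strains, genes,
                                                drop = FALSE])
      subtree <- if (ns < length(tree$tip.label))
        ape::keep.tip(tree, strains) else tree
      traits <- list(); vectors <- list(); tries <- 0L
      while (length(traits) < n_traits && tries < max_retries * n_traits) {
        tries <- tries + 1L
        lt <- tryCatch(random_logic_trait(genes, min(ntg, ng), modularity),
                       error = function(e) NULL)
        if (is.null(lt)) break
        y <- evaluate_logic_trait(lt, sub)
        f <- mean(y)
        if (f >= min_class_fraction && f <= 1 - min_class_fraction) {
          traits[[length(traits) + 1L]] <- lt
          vectors[[length(vectors) + 1L]] <- y
        }
      }
      if (length(traits) < n_traits) {
        list(params = as.list(grid[ci, ]), infeasible = TRUE,
             n_traits_found = length(traits))
      } else {
        tm <- do.call(cbind, vectors)
        colnames(tm) <- sprintf("trait%02d", seq_along(traits))
        structure(list(genotypes = sub, tree = subtree,
                       traits = trait_table(tm), logic_traits = traits,
                       params = c(as.list(grid[ci, ]),
                                  list(modularity = modularity,
                                       seed = cell_seeds[ci])),
                       infeasible = FALSE),
                  class = "synthetic_dataset")
      }
    })
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic dataset: %d strains x %d genes, %d traits (%d trait genes, modularity %.2f)\n",
    nrow(x$genotypes), ncol(x$genotypes), ncol(x$traits), p$n_trait_genes,
    p$modularity %||% 0))
  invisible(x)
}
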