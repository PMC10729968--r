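# Feature selection: conditional-entropy beam search, meta-learning over
# out-of-clade meta-partitions, and reaction-graph (pathway/path/reaction)
# gene selection.

#' Empirical conditional entropy H(y | X) in bits
#'
#' Rows of `X` are grouped by identical gene vector x_s, and
#' `H(y|X) = sum_s P(x = x_s) H(y | x = x_s)` with empirical probabilities
#' (0 log 0 = 0). Zero means the selected genes determine the trait
#' perfectly in-sample; the entropy of y itself is the value reached by an
#' uninformative gene set.
#'
#' @param X_subset binary matrix (strains x selected genes) or vector.
#' @param y 0/1 trait vector aligned with the rows of `X_subset`.
#' @return conditional entropy in bits.
#' @export
conditional_entropy <- function(X_subset, y) {
  if (is.null(dim(X_subset))) X_subset <- matrix(X_subset, ncol = 1)
  m <- nrow(X_subset)
  if (!m || !length(y)) stop("empty input")
  stopifnot(m == length(y), all(y %in% c(0, 1)))
  key <- do.call(paste, c(asplit(X_subset, 2), sep = "\r"))
  tab <- table(key, factor(y, levels = c(0, 1)))
  pk <- rowSums(tab) / m
  py <- tab / pmax(rowSums(tab), 1)
  hly <- -rowSums(ifelse(py > 0, py * log2(py), 0))
  sum(pk * hly)
}

canonical_set <- function(genes) paste(sort(genes), collapse = "\r")

beam_search <- function(genes, score_fun, k_max, beam_width,
                        early_stop_at = NULL) {
  # round r: keep the beam_width best r-gene sets; expand each beam member
  # by every gene not yet in the set; deduplicate unordered sets.
  stopifnot(k_max >= 1, beam_width >= 1)
  k_max <- min(k_max, length(genes))
  beam <- lapply(genes, function(g) g)
  scores <- vapply(beam, score_fun, numeric(1))
  ord <- order(scores)
  best_set <- beam[[ord[1]]]
  best_score <- scores[ord[1]]
  keep <- ord[seq_len(min(beam_width, length(ord)))]
  beam <- beam[keep]; scores <- scores[keep]
  r <- 1L
  while (r < k_max &&
         (is.null(early_stop_at) || best_score > early_stop_at)) {
    cand <- list(); seen <- character(0)
    for (set in beam) for (g in setdiff(genes, set)) {
      key <- canonical_set(c(set, g))
      if (key %in% seen) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- c(set, g)
    }
    if (!length(cand)) break
    cscores <- vapply(cand, score_fun, numeric(1))
    ord <- order(cscores)
    if (cscores[ord[1]] < best_score) {
      best_score <- cscores[ord[1]]
      best_set <- cand[[ord[1]]]
    }
    keep <- ord[seq_len(min(beam_width, length(ord)))]
    beam <- cand[keep]; scores <- cscores[keep]
    r <- r + 1L
  }
  list(set = best_set, score = best_score)
}

#' Greedy beam-search feature selection by conditional entropy
#'
#' Round r keeps the `beam_width` best r-gene sets by conditional entropy
#' and expands each by every gene not yet in the set, stopping at `k_max`
#' genes or as soon as a zero-entropy set is found (adding genes cannot
#' reduce the entropy further). Returns the best set seen at any round, so
#' a perfect pair beats a redundant larger set.
#'
#' @param X binary genotype matrix (strains x genes) with column names.
#' @param y 0/1 trait vector aligned with rows of `X`.
#' @param k_max maximum number of genes; default 5.
#' @param beam_width beam width; default 5.
#' @return object of class `feature_set`: list with `gene_ids`, `score`
#'   (bits), `method = "entropy"`.
#' @export
greedy_entropy_select <- function(X, y, k_max = 5, beam_width = 5) {
  X <- as.matrix(X)
  stopifnot(!is.null(colnames(X)))
  res <- beam_search(colnames(X),
                     function(set) conditional_entropy(X[, set, drop = FALSE], y),
                     k_max, beam_width, early_stop_at = 1e-12)
  structure(list(gene_ids = sort(res$set), score = res$score,
                 method = "entropy"),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set (%s): {%s}, score %.4g\n", x$method,
              paste(x$gene_ids, collapse = ", "), x$score))
  invisible(x)
}

# depth-1 classifier on a single gene: majority y per gene value, fitted on
# (x, y); predicts for new x
stump_fit_predict <- function(x_train, y_train, x_new) {
  pred_for <- function(v) {
    sel <- x_train == v
    if (!any(sel)) return(as.integer(mean(y_train) >= 0.5))
    as.integer(mean(y_train[sel]) >= 0.5)
  }
  map <- c(`0` = pred_for(0L), `1` = pred_for(1L))
  unname(map[as.character(x_new)])
}

tree_fit_predict <- function(X_train, y_train, X_test) {
  df <- data.frame(..y = factor(y_train, levels = c(0, 1)), X_train,
                   check.names = FALSE)
  fit <- rpart::rpart(..y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(minsplit = 2, cp = 0,
                                                     xval = 0))
  p <- predict(fit, newdata = as.data.frame(X_test, check.names = FALSE),
               type = "class")
  as.integer(as.character(p))
}

#' Meta-learning feature selection for out-of-clade generalization
#'
#' Treats out-of-clade prediction as a domain-generalization problem: the
#' training set is itself split into meta-training and meta-test sets by
#' the out-of-clade partitioning rules (`n_meta` partitions), and gene sets
#' are scored by the mean meta-test accuracy of a decision tree using the
#' candidate genes (a depth-1 single-gene classifier in round 1). Beam
#' search proceeds as in [greedy_entropy_select()], the best-scoring set of
#' the final round wins, and a decision tree on the winning set is fitted
#' on the full training data.
#'
#' @param X_train binary matrix of training strains x genes.
#' @param y_train named 0/1 labels for the training strains.
#' @param tree_train phylogeny pruned to the training strains.
#' @param k_max,beam_width beam-search parameters; defaults 5 and 5.
#' @param n_meta number of meta-partitions; default 20.
#' @param min_fraction,max_fraction out-of-clade size range for the
#'   meta-partitions; defaults 0.10 and 0.30.
#' @param seed RNG seed.
#' @return a `feature_set` (score = mean meta-test accuracy) with the
#'   fitted `model` (an rpart tree) and a `predict_fun(X_new)` closure.
#' @export
meta_learning_select <- function(X_train, y_train, tree_train, k_max = 5,
                                 n_meta = 20, beam_width = 5,
                                 min_fraction = 0.1, max_fraction = 0.3,
                                 seed = NULL) {
  X_train <- as.matrix(X_train)
  stopifnot(!is.null(colnames(X_train)), !is.null(rownames(X_train)))
  if (is.null(names(y_train))) names(y_train) <- rownames(X_train)
  cands <- tryCatch(
    enumerate_clade_testsets(tree_train, min_fraction, max_fraction),
    error = function(e) stop("meta-partition enumeration failed: ",
                             conditionMessage(e)))
  seeds <- derive_seeds(seed %||% 0L, n_meta)
  metas <- lapply(seeds, function(s)
    out_of_clade_partition(tree_train, min_fraction, max_fraction,
                           seed = s, candidates = cands))
  # drop meta-partitions whose meta-training labels are single-class
  usable <- vapply(metas, function(p)
    length(unique(y_train[p$train_ids])) == 2, logical(1))
  metas <- metas[usable]
  if (!length(metas)) stop("no usable meta-partition (single-class labels)")
  score_fun <- function(set) {
    accs <- vapply(metas, function(p) {
      ytr <- as.integer(y_train[p$train_ids])
      yte <- as.integer(y_train[p$test_ids])
      if (length(set) == 1L) {
        pred <- stump_fit_predict(X_train[p$train_ids, set], ytr,
                                  X_train[p$test_ids, set])
      } else {
        pred <- tree_fit_predict(X_train[p$train_ids, set, drop = FALSE],
                                 ytr,
                                 X_train[p$test_ids, set, drop = FALSE])
      }
      mean(pred == yte)
    }, numeric(1))
    -mean(accs)  # beam_search minimizes
  }
  res <- beam_search(colnames(X_train), score_fun, k_max, beam_width)
  set <- res$set
  df <- data.frame(..y = factor(as.integer(y_train[rownames(X_train)]),
                                levels = c(0, 1)),
                   X_train[, set, drop = FALSE], check.names = FALSE)
  final <- rpart::rpart(..y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(minsplit = 2, cp = 0,
                                                       xval = 0))
  predict_fun <- function(X_new) {
    if (length(set) == 1L) {
      stump_fit_predict(X_train[, set], as.integer(y_train[rownames(X_train)]),
                        as.matrix(X_new)[, set])
    } else {
      p <- predict(final, newdata = as.data.frame(as.matrix(X_new),
                                                  check.names = FALSE),
                   type = "class")
      as.integer(as.character(p))
    }
  }
  structure(list(gene_ids = sort(set), score = -res$score, method = "meta",
                 model = final, predict_fun = predict_fun,
                 n_meta_used = length(metas)),
            class = "feature_set")
}

# ---- reaction graph ---------------------------------------------------

#' Read a reaction graph from JSON
#'
#' The JSON object must contain `compounds` (array of compound IDs),
#' `reactions` (array of objects with `id`, `substrate`, `product`, `kos`),
#' `pathways` (map from pathway ID to an object with `compounds` and
#' `kos`), and optionally `destinations` (array of central-metabolism
#' compound IDs used as default path targets).
#'
#' @param path JSON file.
#' @return object of class `reaction_graph`.
#' @export
read_reaction_graph <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  reactions <- lapply(raw$reactions, function(r)
    list(id = r$id, substrate = r$substrate, product = r$product,
         kos = as.character(unlist(r$kos))))
  reaction_graph(compounds = as.character(raw$compounds),
                 reactions = reactions,
                 pathways = raw$pathways,
                 destinations = as.character(raw$destinations %||% character(0)))
}

#' Construct a reaction graph
#'
#' Nodes are metabolites; each directed edge is a reaction from substrate
#' to product carrying a (possibly empty) set of gene-ortholog IDs.
#'
#' @param compounds character vector of compound IDs.
#' @param reactions list of lists with `id`, `substrate`, `product`, `kos`.
#' @param pathways named list: pathway ID -> list with `compounds`, `kos`.
#' @param destinations default destination compounds for path queries.
#' @return object of class `reaction_graph`.
#' @export
reaction_graph <- function(compounds, reactions, pathways = list(),
                           destinations = character(0)) {
  for (r in reactions) {
    if (!r$substrate %in% compounds || !r$product %in% compounds)
      stop(sprintf("reaction '%s' references unknown compounds", r$id))
  }
  structure(list(compounds = compounds, reactions = reactions,
                 pathways = pathways, destinations = destinations),
            class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat(sprintf("Reaction graph: %d compounds, %d reactions, %d pathways\n",
              length(x$compounds), length(x$reactions), length(x$pathways)))
  invisible(x)
}

rg_igraph <- function(graph, directed = TRUE) {
  edges <- vapply(graph$reactions, function(r) c(r$substrate, r$product),
                  character(2))
  g <- igraph::make_empty_graph(directed = directed) +
    igraph::vertices(graph$compounds)
  g <- igraph::add_edges(g, as.vector(edges),
                         reaction = vapply(graph$reactions, `[[`, "", "id"))
  g
}

#' Select genes for a carbon source from a reaction graph
#'
#' Three levels of specificity:
#' * `"pathways"` — union of the gene sets of all pathways whose compound
#'   list contains the carbon source;
#' * `"paths"` — enumerate loopless paths (Yen's k-shortest-paths, path
#'   length = number of reaction steps) from the carbon source to any
#'   destination compound, take the `top_k_paths` shortest over all
#'   destinations (ties broken by the lexicographic order of the node
#'   sequences), and return the union of the gene sets of the traversed
#'   reactions;
#' * `"reactions"` — union of the gene sets of reactions incident to the
#'   carbon source as substrate or product.
#'
#' @param graph a `reaction_graph`.
#' @param carbon compound ID of the carbon source.
#' @param level `"pathways"`, `"paths"`, or `"reactions"`.
#' @param top_k_paths number of shortest paths to use; default 3 (fewer are
#'   used if fewer exist).
#' @param directed traverse reactions substrate-to-product only (TRUE,
#'   default) or bidirectionally (FALSE).
#' @param destinations destination compounds for `"paths"`; defaults to the
#'   graph's own destination list.
#' @return sorted character vector of gene IDs (possibly empty, with a
#'   warning when no path reaches a destination).
#' @export
kegg_select <- function(graph, carbon,
                        level = c("pathways", "paths", "reactions"),
                        top_k_paths = 3, directed = TRUE,
                        destinations = NULL) {
  stopifnot(inherits(graph, "reaction_graph"), top_k_paths >= 1)
  level <- match.arg(level)
  if (!carbon %in% graph$compounds)
    stop(sprintf("compound '%s' absent from reaction graph", carbon))
  if (level == "pathways") {
    kos <- unlist(lapply(graph$pathways, function(pw)
      if (carbon %in% unlist(pw$compounds)) unlist(pw$kos) else NULL))
    return(sort(unique(as.character(kos))))
  }
  if (level == "reactions") {
    kos <- unlist(lapply(graph$reactions, function(r)
      if (r$substrate == carbon || r$product == carbon) r$kos else NULL))
    return(sort(unique(as.character(kos))))
  }
  # level == "paths"
  destinations <- destinations %||% graph$destinations
  destinations <- setdiff(intersect(destinations, graph$compounds), carbon)
  if (!length(destinations)) {
    warning("no destination compounds available")
    return(character(0))
  }
  g <- rg_igraph(graph, directed = directed)
  paths <- list()
  for (dest in destinations) {
    res <- tryCatch(
      suppressWarnings(igraph::k_shortest_paths(g, from = carbon, to = dest,
                                                k = top_k_paths)),
      error = function(e) list(vpaths = list(), epaths = list()))
    for (i in seq_along(res$vpaths)) {
      paths[[length(paths) + 1L]] <- list(
        nodes = names(res$vpaths[[i]]),
        edges = as.integer(res$epaths[[i]]))
    }
  }
  if (!length(paths)) {
    warning(sprintf("no path from '%s' to any destination", carbon))
    return(character(0))
  }
  lens <- vapply(paths, function(p) length(p$edges), integer(1))
  keys <- vapply(paths, function(p) paste(p$nodes, collapse = "\r"),
                 character(1))
  ord <- order(lens, keys)
  ord <- ord[!duplicated(keys[ord])]
  use <- ord[seq_len(min(top_k_paths, length(ord)))]
  eids <- unique(unlist(lapply(paths[use], `[[`, "edges")))
  rids <- igraph::edge_attr(g, "reaction", eids)
  kos <- unlist(lapply(graph$reactions,
                       function(r) if (r$id %in% rids) r$kos else NULL))
  sort(unique(as.character(kos)))
}
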