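# Benchmark orchestration: run traits x models x regimes over many
# partitions, evaluate against both null models with the permutation-test
# protocol, and summarize.

#' Build a benchmark configuration
#'
#' @param genotypes a [genotype_matrix()] (or path to a TSV).
#' @param traits a [trait_table()] (or path to a TSV).
#' @param tree a `phylo` tree (or path to a Newick file).
#' @param models character subset of `"nn"`, `"rf"`, `"logreg"`; default
#'   `c("nn", "rf")`.
#' @param regimes character subset of `"random"`, `"out_of_clade"`.
#' @param n_partitions partitions per trait x regime; default 100.
#' @param test_fraction random-partition holdout fraction; default 0.2.
#' @param min_fraction,max_fraction out-of-clade test-size range; defaults
#'   0.10 and 0.30.
#' @param min_per_class trait filter threshold (see [filter_traits()]);
#'   default 10.
#' @param alpha significance level; default 0.05.
#' @param n_permutations permutation-test budget; default 1e5.
#' @param nn_metric distance for the nearest-neighbor model: `"l1"`
#'   (genotype) or `"patristic"` (tree); default `"l1"`.
#' @param rf_config hyperparameters for [rf_fit_predict()].
#' @param feature_selection `"none"` (default), `"entropy"` or `"meta"`;
#'   applied per partition on the training data before fitting.
#' @param fs_k_max,fs_beam_width,fs_n_meta feature-selection parameters.
#' @param seed master RNG seed.
#' @return a `benchmark_config` list.
#' @export
benchmark_config <- function(genotypes, traits, tree,
                             models = c("nn", "rf"),
                             regimes = c("random", "out_of_clade"),
                             n_partitions = 100, test_fraction = 0.2,
                             min_fraction = 0.1, max_fraction = 0.3,
                             min_per_class = 10, alpha = 0.05,
                             n_permutations = 1e5, nn_metric = "l1",
                             rf_config = list(),
                             feature_selection = "none", fs_k_max = 5,
                             fs_beam_width = 5, fs_n_meta = 20,
                             seed = 1) {
  if (is.character(genotypes)) genotypes <- load_genotype_matrix(genotypes)
  if (is.character(traits)) traits <- load_trait_table(traits)
  if (is.character(tree)) tree <- load_tree(tree)
  stopifnot(all(models %in% c("nn", "rf", "logreg")),
            all(regimes %in% c("random", "out_of_clade")),
            n_partitions >= 2,
            feature_selection %in% c("none", "entropy", "meta"))
  structure(list(genotypes = genotypes, traits = traits, tree = tree,
                 models = models, regimes = regimes,
                 n_partitions = n_partitions, test_fraction = test_fraction,
                 min_fraction = min_fraction, max_fraction = max_fraction,
                 min_per_class = min_per_class, alpha = alpha,
                 n_permutations = n_permutations, nn_metric = nn_metric,
                 rf_config = rf_config,
                 feature_selection = feature_selection,
                 fs_k_max = fs_k_max, fs_beam_width = fs_beam_width,
                 fs_n_meta = fs_n_meta, seed = seed),
            class = "benchmark_config")
}

#' Load a benchmark configuration from YAML
#'
#' The YAML file holds the scalar settings of [benchmark_config()] plus
#' `genotypes`, `traits`, `tree` file paths (resolved relative to the YAML
#' file's directory).
#'
#' @param path YAML file.
#' @return a `benchmark_config`.
#' @export
load_benchmark_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  for (f in c("genotypes", "traits", "tree")) {
    if (is.null(cfg[[f]])) stop("config misses required field: ", f)
    cfg[[f]] <- resolve(cfg[[f]])
    if (!file.exists(cfg[[f]])) stop("file not found: ", cfg[[f]])
  }
  do.call(benchmark_config, cfg)
}

fit_model_partition <- function(model, cfg, X, y, dist_nn, part, seed) {
  tr <- part$train_ids
  te <- part$test_ids
  genes <- colnames(X)
  if (cfg$feature_selection != "none" && model != "nn") {
    if (cfg$feature_selection == "entropy") {
      fs <- greedy_entropy_select(X[tr, , drop = FALSE], y[tr],
                                  cfg$fs_k_max, cfg$fs_beam_width)
      genes <- fs$gene_ids
    } else {
      tree_tr <- ape::keep.tip(cfg$tree, tr)
      fs <- meta_learning_select(X[tr, , drop = FALSE], y[tr], tree_tr,
                                 k_max = cfg$fs_k_max,
                                 n_meta = cfg$fs_n_meta,
                                 beam_width = cfg$fs_beam_width,
                                 min_fraction = cfg$min_fraction,
                                 max_fraction = cfg$max_fraction,
                                 seed = seed)
      preds <- as.integer(fs$predict_fun(X[te, , drop = FALSE]))
      names(preds) <- te
      return(new_fit_result(preds, "meta", partition = part))
    }
  }
  switch(model,
    nn = nn_predict(dist_nn, tr, y[tr], te),
    rf = rf_fit_predict(X[tr, genes, drop = FALSE], y[tr],
                        X[te, genes, drop = FALSE], cfg$rf_config, seed),
    logreg = logreg_l1_fit_predict(X[tr, genes, drop = FALSE], y[tr],
                                   X[te, genes, drop = FALSE]))
}

#' Run a full benchmark
#'
#' For every trait passing [filter_traits()], every requested regime and
#' model: generate `n_partitions` train/test partitions on the usable
#' strains (those with a non-missing trait value), fit and score the model
#' and both null models on identical partitions, then test the model's
#' accuracy distribution against each null with a two-sided permutation
#' t-test. Raw p-values are corrected jointly across all traits of the run
#' (per model x regime x null family) with [holm_sidak()]; a trait is
#' called significant when both corrected p-values fall below `alpha` and
#' the model's mean accuracy exceeds both null means. Random-forest
#' importances are averaged across partitions.
#'
#' @param config a `benchmark_config` (or path to a YAML file).
#' @return object of class `benchmark_result`: list with `detail` (one row
#'   per trait x model x regime x partition), `comparisons` (one row per
#'   trait x model x regime), `importance` (named list of
#'   importance profiles), `partitions`, `skipped`, `config`.
#' @export
run_benchmark <- function(config) {
  if (is.character(config)) config <- load_benchmark_config(config)
  stopifnot(inherits(config, "benchmark_config"))
  cfg <- config
  traits <- filter_traits(cfg$traits, cfg$min_per_class)
  skipped <- setdiff(colnames(cfg$traits), colnames(traits))
  X <- cfg$genotypes
  dist_nn <- if ("nn" %in% cfg$models && cfg$nn_metric == "patristic")
    distance_matrix(cfg$tree) else distance_matrix(X, "l1")
  detail <- list(); comparisons <- list()
  importance <- list(); partition_log <- list()
  trait_ids <- colnames(traits)
  master_seeds <- derive_seeds(cfg$seed, max(1L, length(trait_ids)))
  for (ti in seq_along(trait_ids)) {
    trait_id <- trait_ids[ti]
    y_all <- unclass(traits)[, trait_id]
    usable <- rownames(traits)[!is.na(y_all)]
    y <- as.integer(y_all[usable]); names(y) <- usable
    tree_u <- if (length(usable) < length(cfg$tree$tip.label))
      ape::keep.tip(cfg$tree, usable) else cfg$tree
    seeds <- derive_seeds(master_seeds[ti],
                          2L * cfg$n_partitions + length(cfg$regimes))
    for (ri in seq_along(cfg$regimes)) {
      regime <- cfg$regimes[ri]
      cands <- if (regime == "out_of_clade")
        enumerate_clade_testsets(tree_u, cfg$min_fraction, cfg$max_fraction)
      else NULL
      parts <- lapply(seq_len(cfg$n_partitions), function(i) {
        s <- seeds[(ri - 1L) * cfg$n_partitions + i]
        if (regime == "random")
          random_partition(usable, cfg$test_fraction, seed = s)
        else
          out_of_clade_partition(tree_u, cfg$min_fraction,
                                 cfg$max_fraction, seed = s,
                                 candidates = cands)
      })
      partition_log[[paste(trait_id, regime, sep = ".")]] <- parts
      # null accuracies, shared across models
      null_acc <- lapply(seq_along(parts), function(i) {
        p <- parts[[i]]
        yte <- y[p$test_ids]
        bp <- bernoulli_null_predict(y[p$train_ids], length(yte),
                                     seed = seeds[length(seeds)] + i)
        ip <- identity_null_predict(y[p$train_ids], length(yte))
        c(bern = mean(bp == yte), ident = mean(ip == yte))
      })
      bern_acc <- vapply(null_acc, `[[`, numeric(1), "bern")
      ident_acc <- vapply(null_acc, `[[`, numeric(1), "ident")
      for (model in cfg$models) {
        fits <- lapply(seq_along(parts), function(i) {
          p <- parts[[i]]
          if (length(unique(y[p$train_ids])) < 2) return(NULL)
          fit_model_partition(model, cfg, X, y, dist_nn, p,
                              seed = seeds[i] + 1L)
        })
        ok <- !vapply(fits, is.null, logical(1))
        accs <- rep(NA_real_, length(parts))
        bals <- rep(NA_real_, length(parts))
        for (i in which(ok)) {
          sc <- score(fits[[i]]$predictions, y[parts[[i]]$test_ids])
          accs[i] <- sc$accuracy
          bals[i] <- sc$balanced_accuracy
        }
        detail[[length(detail) + 1L]] <- data.frame(
          trait = trait_id, model = model, regime = regime,
          partition = seq_along(parts), accuracy = accs,
          balanced_accuracy = bals, bernoulli_accuracy = bern_acc,
          identity_accuracy = ident_acc)
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          trait = trait_id, model = model, regime = regime,
          n_partitions = sum(ok), mean_accuracy = mean(accs[ok]),
          mean_balanced_accuracy = mean(bals[ok], na.rm = TRUE),
          mean_bernoulli = mean(bern_acc[ok]),
          mean_identity = mean(ident_acc[ok]),
          p_bernoulli = if (sum(ok) >= 2)
            permutation_t_test(accs[ok], bern_acc[ok],
                               cfg$n_permutations,
                               seed = seeds[length(seeds) - 1L])
          else NA_real_,
          p_identity = if (sum(ok) >= 2)
            permutation_t_test(accs[ok], ident_acc[ok],
                               cfg$n_permutations,
                               seed = seeds[length(seeds) - 1L] + 1L)
          else NA_real_)
        if (model == "rf" && any(ok))
          importance[[paste(trait_id, regime, sep = ".")]] <-
            aggregate_importance(fits[ok])
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
  else data.frame()
  if (nrow(comparisons)) {
    comparisons$p_bernoulli_adj <- NA_real_
    comparisons$p_identity_adj <- NA_real_
    # joint step-down correction across traits, per model x regime family
    for (model in unique(comparisons$model))
      for (regime in unique(comparisons$regime)) {
        sel <- comparisons$model == model & comparisons$regime == regime &
          !is.na(comparisons$p_bernoulli)
        if (!any(sel)) next
        comparisons$p_bernoulli_adj[sel] <-
          holm_sidak(comparisons$p_bernoulli[sel])
        comparisons$p_identity_adj[sel] <-
          holm_sidak(comparisons$p_identity[sel])
      }
    comparisons$significant <-
      !is.na(comparisons$p_bernoulli_adj) &
      comparisons$p_bernoulli_adj < cfg$alpha &
      comparisons$p_identity_adj < cfg$alpha &
      comparisons$mean_accuracy > comparisons$mean_bernoulli &
      comparisons$mean_accuracy > comparisons$mean_identity
  }
  structure(list(detail = if (length(detail)) do.call(rbind, detail)
                 else data.frame(),
                 comparisons = comparisons, importance = importance,
                 partitions = partition_log, skipped = skipped,
                 config = cfg),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: %d trait/model/regime cells, %d skipped traits\n",
              nrow(x$comparisons), length(x$skipped)))
  if (nrow(x$comparisons)) print(summarize_benchmark(x))
  invisible(x)
}

#' One-row-per-cell benchmark summary
#'
#' @param result a `benchmark_result` from [run_benchmark()].
#' @return data.frame with one row per trait x model x regime: mean
#'   accuracies, null means, corrected p-values and the significance flag;
#'   zero rows (stable schema) when the benchmark was empty.
#' @export
summarize_benchmark <- function(result) {
  stopifnot(inherits(result, "benchmark_result"))
  cols <- c("trait", "model", "regime", "n_partitions", "mean_accuracy",
            "mean_balanced_accuracy", "mean_bernoulli", "mean_identity",
            "p_bernoulli_adj", "p_identity_adj", "significant")
  cmp <- result$comparisons
  if (!nrow(cmp)) {
    out <- data.frame(trait = character(0), model = character(0),
                      regime = character(0), n_partitions = integer(0),
                      mean_accuracy = numeric(0),
                      mean_balanced_accuracy = numeric(0),
                      mean_bernoulli = numeric(0),
                      mean_identity = numeric(0),
                      p_bernoulli_adj = numeric(0),
                      p_identity_adj = numeric(0),
                      significant = logical(0))
    return(out)
  }
  cmp[, cols]
}

#' Count significant traits per model and regime
#'
#' @param result a `benchmark_result`.
#' @return data.frame with `model`, `regime`, `n_traits`,
#'   `n_significant`.
#' @export
tally_significant <- function(result) {
  cmp <- result$comparisons
  if (!nrow(cmp))
    return(data.frame(model = character(0), regime = character(0),
                      n_traits = integer(0), n_significant = integer(0)))
  agg <- aggregate(cbind(n_significant = significant) ~ model + regime,
                   data = cmp, FUN = sum)
  cnt <- aggregate(cbind(n_traits = significant) ~ model + regime,
                   data = cmp, FUN = length)
  merge(cnt, agg)
}

#' Write benchmark outputs to a directory
#'
#' Writes `summary.tsv` (one row per trait x model x regime),
#' `importance.tsv` (mean importances, long format) and `detail.json`
#' (per-partition accuracies).
#'
#' @param result a `benchmark_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(summarize_benchmark(result), file.path(dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(result$importance)) {
    imp <- do.call(rbind, lapply(names(result$importance), function(k) {
      pr <- result$importance[[k]]
      data.frame(cell = k, gene = pr$gene_ids,
                 mean_importance = unname(pr$mean_importance),
                 n_partitions = pr$n_partitions)
    }))
    write.table(imp, file.path(dir, "importance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$detail, file.path(dir, "detail.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
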