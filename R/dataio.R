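# Data IO: genotype matrices, trait tables, trees, distances, and the
# raw growth-assay binarization and trait-filtering rules.

#' Construct a genotype matrix
#'
#' A genotype matrix is a binary strains x genes presence/absence matrix
#' with unique strain and gene identifiers and no missing entries. It is the
#' universal predictor object of the package.
#'
#' @param values matrix (or data.frame) of 0/1 values with row names = strain
#'   IDs and column names = gene IDs.
#' @return an integer matrix of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("genotype matrix needs strain row names and gene column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate strain IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("genotype matrix must not contain missing values")
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(values)) + 1L
    stop(sprintf("non-binary value %s at strain '%s', gene '%s'",
                 format(values[i, j]), rownames(values)[i], colnames(values)[j]))
  }
  storage.mode(values) <- "integer"
  structure(values, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d strains x %d genes (density %.3f)\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Construct a trait table
#'
#' A trait table is a strains x traits matrix of binary phenotypes (e.g.
#' growth/no-growth on a carbon source); entries may be `NA` where a
#' measurement is missing or was discarded as inconsistent.
#'
#' @param values matrix of 0/1/NA with strain row names and trait column
#'   names.
#' @return an integer matrix of class `"trait_table"`.
#' @export
trait_table <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("trait table needs strain row names")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("trait table needs trait column names")
  if (anyDuplicated(rownames(values))) stop("duplicate strain IDs")
  if (anyDuplicated(colnames(values))) stop("duplicate trait IDs")
  ok <- values %in% c(0, 1) | is.na(values)
  if (!all(ok)) stop("trait values must be 0, 1 or NA")
  storage.mode(values) <- "integer"
  structure(values, class = c("trait_table", "matrix", "array"))
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Trait table: %d strains x %d traits (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read a genotype matrix from TSV
#'
#' Expects a tab-separated table with a header row of gene IDs and a first
#' column of strain IDs. Cells must be 0 or 1.
#'
#' @param path file path.
#' @return a [genotype_matrix()].
#' @export
load_genotype_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1,
                   colClasses = "character")
  ch <- as.matrix(df)
  m <- suppressWarnings(matrix(as.numeric(ch), nrow = nrow(ch),
                               dimnames = list(rownames(df), colnames(df))))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at strain '%s', gene '%s'",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  genotype_matrix(m)
}

#' Write a genotype matrix to TSV
#' @param x a genotype_matrix.
#' @param path file path.
#' @export
write_genotype_matrix <- function(x, path) {
  write_tsv_matrix(unclass(x), path)
}

#' Read a trait table from TSV (missing entries as "NA")
#' @param path file path.
#' @return a [trait_table()].
#' @export
load_trait_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  trait_table(m)
}

#' Write a trait table to TSV
#' @param x a trait_table.
#' @param path file path.
#' @export
write_trait_table <- function(x, path) {
  write_tsv_matrix(unclass(x), path)
}

write_tsv_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a rooted phylogenetic tree
#'
#' Thin wrapper over [ape::read.tree()] that validates the properties the
#' rest of the package relies on: unique leaf labels and finite,
#' non-negative branch lengths.
#'
#' @param path Newick file.
#' @return an `ape` `phylo` object.
#' @export
load_tree <- function(path) {
  tree <- ape::read.tree(path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  invisible(tree)
}

#' Binarize raw growth measurements
#'
#' Each strain x condition combination is measured as two technical
#' replicate optical densities. Growth is called when both replicates reach
#' the threshold, no-growth when both fall below it, and the entry is
#' discarded (NA) when the two replicates disagree after binarization.
#'
#' @param od_table data.frame with columns `strain`, `condition`, `od1`,
#'   `od2` (two replicate OD readings).
#' @param threshold OD threshold calling growth; default 0.2.
#' @return a [trait_table()] with one column per condition.
#' @export
binarize_growth <- function(od_table, threshold = 0.2) {
  stopifnot(is.data.frame(od_table),
            all(c("strain", "condition", "od1", "od2") %in% names(od_table)),
            threshold > 0)
  if (any(od_table$od1 < 0) || any(od_table$od2 < 0))
    stop("negative OD reading")
  b1 <- as.integer(od_table$od1 >= threshold)
  b2 <- as.integer(od_table$od2 >= threshold)
  val <- ifelse(b1 == b2, b1, NA_integer_)
  strains <- unique(od_table$strain)
  conds <- unique(od_table$condition)
  m <- matrix(NA_integer_, length(strains), length(conds),
              dimnames = list(strains, conds))
  m[cbind(match(od_table$strain, strains),
          match(od_table$condition, conds))] <- val
  trait_table(m)
}

#' Drop traits without enough strains in both classes
#'
#' Keeps only traits with at least `min_per_class` non-missing 0s and at
#' least `min_per_class` non-missing 1s, so that model evaluation has
#' variance to work with.
#'
#' @param traits a trait_table.
#' @param min_per_class minimum count per class; default 10.
#' @return the filtered trait_table (possibly with zero columns).
#' @export
filter_traits <- function(traits, min_per_class = 10) {
  stopifnot(inherits(traits, "trait_table"), min_per_class >= 1)
  n1 <- colSums(traits == 1, na.rm = TRUE)
  n0 <- colSums(traits == 0, na.rm = TRUE)
  keep <- n1 >= min_per_class & n0 >= min_per_class
  trait_table(unclass(traits)[, keep, drop = FALSE])
}

#' Pairwise distance matrix
#'
#' Computes the symmetric distance matrix used by nearest-neighbor
#' classification and by the phylogenetic-signal statistics:
#' * `patristic` — sum of branch lengths on the tree path between two
#'   leaves (input: `phylo` tree);
#' * `hamming` — raw count of mismatching columns between two aligned
#'   sequences; a gap counts as an ordinary symbol (input: character matrix
#'   of an alignment, rows = strains);
#' * `l1` — count of differing entries between two binary gene
#'   presence/absence vectors (input: genotype_matrix). For binary vectors
#'   this equals the Hamming distance.
#'
#' @param data a `phylo` tree, an alignment character matrix, or a
#'   genotype_matrix.
#' @param metric one of `"patristic"`, `"hamming"`, `"l1"`; default chosen
#'   from the input type.
#' @return a numeric matrix of class `"dist_matrix"` with attribute
#'   `metric`.
#' @export
distance_matrix <- function(data, metric = NULL) {
  if (inherits(data, "phylo")) {
    metric <- metric %||% "patristic"
    if (metric != "patristic") stop("trees support only the patristic metric")
    validate_tree(data)
    m <- ape::cophenetic.phylo(data)
    m <- m[order(rownames(m)), order(colnames(m))]
  } else if (inherits(data, "genotype_matrix")) {
    metric <- metric %||% "l1"
    if (!metric %in% c("l1", "hamming"))
      stop("binary matrices support the l1 (= hamming) metric")
    m <- l1_dist(unclass(data))
    metric <- "l1"
  } else if (is.matrix(data) && is.character(data)) {
    metric <- metric %||% "hamming"
    if (metric != "hamming") stop("alignments support only the hamming metric")
    if (is.null(rownames(data))) stop("alignment needs strain row names")
    m <- hamming_dist(data)
  } else {
    stop("unsupported input type for distance_matrix")
  }
  structure(m, class = c("dist_matrix", "matrix", "array"), metric = metric)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

l1_dist <- function(x) {
  # |a-b| summed over binary entries: a(1-b) + b(1-a)
  x <- matrix(as.numeric(x), nrow(x), dimnames = dimnames(x))
  s <- x %*% t(1 - x)
  m <- s + t(s)
  diag(m) <- 0
  m
}

hamming_dist <- function(aln) {
  n <- nrow(aln)
  if (n >= 2) {
    lens <- apply(aln, 1, function(r) sum(!is.na(r)))
    if (anyNA(aln) || length(unique(lens)) > 1)
      stop("sequences must be aligned to equal length")
  }
  m <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    d <- sum(aln[i, ] != aln[j, ])
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Read an aligned FASTA file as a character matrix
#'
#' @param path aligned FASTA file; all sequences must have equal length.
#' @return character matrix, rows named by sequence ID.
#' @export
load_alignment <- function(path) {
  seqs <- ape::read.FASTA(path)
  ch <- as.character(seqs)
  lens <- lengths(ch)
  if (length(unique(lens)) > 1)
    stop("sequences must be aligned to equal length")
  m <- do.call(rbind, ch)
  rownames(m) <- names(ch)
  m
}
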