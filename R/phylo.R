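# Distance matrices, neighbor-joining trees, bootstrap bipartition support
# and newick I/O. Tree objects are ape "phylo"; bootstrap support is stored
# both in node labels and in a per-split table (attribute "splits").

#' Pairwise distance matrix from an alignment
#'
#' Gap columns are deleted pairwise; `p` is the fraction of mismatching
#' compared columns. The Poisson correction is `d = -ln(1 - p)`.
#'
#' @param msa An `alignment` object (>= 2 rows).
#' @param model `"p_distance"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with taxon dimnames and a `model`
#'   attribute. Poisson distances with `p >= 1` are `NA` with a warning.
#' @export
distance_matrix <- function(msa, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  if (length(msa$rows) < 2L) stop("need at least two rows")
  M <- .msa_int_matrix(msa)
  D <- .pdist_int(M, model)
  attr(D, "model") <- model
  D
}

# integer matrix taxa x columns, 0 = gap
.msa_int_matrix <- function(msa) {
  ch <- strsplit(unname(msa$rows), "")
  m <- do.call(rbind, ch)
  sym <- sort(unique(as.vector(m)))
  out <- matrix(match(m, sym), nrow = nrow(m),
                dimnames = list(msa$ids, NULL))
  out[m == "-"] <- 0L
  out
}

.pdist_int <- function(M, model = "p_distance") {
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  nz <- M != 0L
  for (i in seq_len(n - 1L)) {
    xi <- M[i, ]
    vi <- nz[i, ]
    for (j in (i + 1L):n) {
      valid <- vi & nz[j, ]
      nc <- sum(valid)
      if (nc == 0L)
        stop("no shared non-gap columns between rows ", i, " and ", j)
      p <- sum(xi[valid] != M[j, valid]) / nc
      D[i, j] <- D[j, i] <- p
    }
  }
  if (model == "poisson") {
    bad <- D >= 1
    if (any(bad)) {
      warning("Poisson distance undefined (p >= 1) for ",
              sum(bad) / 2, " pair(s); set to NA")
      D[bad] <- NA_real_
    }
    ok <- !is.na(D)
    D[ok] <- -log(1 - D[ok])
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix. Negative
#' branch lengths are clamped to zero with a warning.
#'
#' @param dm Symmetric nonnegative matrix with zero diagonal and taxon
#'   dimnames (n >= 2).
#' @return An unrooted `phylo` tree (for n = 2, the two tips joined by a
#'   single path of total length `d(1,2)`).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need at least two taxa")
  if (is.null(rownames(dm))) stop("distance matrix must have taxon names")
  if (any(is.na(dm))) stop("distance matrix contains NA")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (n == 2L) {
    tr <- structure(list(
      edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
      edge.length = rep(dm[1, 2] / 2, 2),
      tip.label = rownames(dm), Nnode = 1L
    ), class = "phylo", order = "cladewise")
    return(tr)
  }
  tr <- ape::nj(dm)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap bipartition support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance
#' matrix and NJ tree per replicate, and scores each internal edge of the
#' full-data tree by the percentage of replicate trees containing the same
#' leaf bipartition. Deterministic for a given `seed`.
#'
#' @param msa An `alignment` (>= 2 columns).
#' @param model Distance model, as in [distance_matrix()].
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @return The full-data NJ `phylo` tree with supports (percent, rounded to
#'   one decimal) as node labels and a `data.frame` attribute `"splits"`
#'   with columns `node`, `key`, `support`.
#' @export
bootstrap_support <- function(msa, model = "p_distance",
                              replicates = 1000L, seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  M <- .msa_int_matrix(msa)
  L <- ncol(M)
  if (L < 2L) stop("alignment must have at least 2 columns")
  main <- nj_tree(.pdist_int(M, model))
  main_splits <- .tree_splits(main)

  set.seed(seed)
  seen <- character(0)
  for (r in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    tr <- ape::nj(.pdist_int(M[, idx, drop = FALSE], model))
    seen <- c(seen, unique(.tree_splits(tr)$key))
  }
  counts <- table(seen)
  supp <- 100 * as.numeric(counts[main_splits$key]) / replicates
  supp[is.na(supp)] <- 0
  main_splits$support <- supp

  ntip <- length(main$tip.label)
  lab <- rep("", main$Nnode)
  lab[main_splits$node - ntip] <- format(round(supp, 1), trim = TRUE)
  main$node.label <- lab
  attr(main, "splits") <- main_splits
  main
}

# canonical nontrivial bipartitions of a phylo tree:
# data.frame(node, key) where key is the sorted leaf set on the side not
# containing the alphabetically first taxon, joined by "\r"
.tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- min(labs)
  out_node <- integer(0)
  out_key <- character(0)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(labs, side)
    out_node <- c(out_node, ntip + k)
    out_key <- c(out_key, paste(sort(side), collapse = "\r"))
  }
  data.frame(node = out_node, key = out_key, stringsAsFactors = FALSE)
}

# canonical key for the bipartition separating `leaves` from the rest
.split_key <- function(leaves, all_taxa) {
  side <- sort(intersect(leaves, all_taxa))
  if (min(all_taxa) %in% side) side <- sort(setdiff(all_taxa, side))
  paste(side, collapse = "\r")
}

#' Nontrivial bipartitions of a tree
#'
#' @param tree A `phylo` tree.
#' @return A list of splits; each element is a list with components `a` and
#'   `b` (the two leaf sets, both of size >= 2). A star tree yields an
#'   empty list; a binary unrooted n-leaf tree yields n - 3 splits.
#' @export
bipartitions <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  sp <- unique(.tree_splits(ape::unroot(tree))["key"])
  taxa <- tree$tip.label
  lapply(sp$key, function(k) {
    a <- strsplit(k, "\r", fixed = TRUE)[[1]]
    list(a = a, b = sort(setdiff(taxa, a)))
  })
}

#' Read / write newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]; bootstrap
#' supports travel as internal node labels, branch lengths after colons.
#'
#' @param path File path.
#' @param tree A `phylo` tree (for writing).
#' @return `read_newick` returns a `phylo`; `write_newick` its path,
#'   invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
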