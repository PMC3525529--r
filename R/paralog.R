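# Detection of bootstrap-supported same-species paralog groups and
# classification of joint two-species subtrees as species-specific
# (reciprocally monophyletic) versus interleaved.

#' Find supported same-species paralog groups
#'
#' Scans the clades of a (rooted) tree for maximal groups of at least
#' `min_size` genes that all belong to one species and whose subtending
#' edge carries bootstrap support of at least `min_support` percent.
#' Reported groups are maximal: no reported group is nested inside another.
#'
#' @param tree A `phylo` tree, normally rooted (e.g. by an outgroup), with
#'   bootstrap supports attached by [bootstrap_support()].
#' @param species_of Named character vector mapping every leaf id to its
#'   species.
#' @param min_size Minimum number of genes in a group (default 4).
#' @param min_support Minimum bootstrap percentage on the subtending edge
#'   (default 90).
#' @param splits Optional support table (`data.frame` with `key`,
#'   `support`) as produced by [bootstrap_support()]; defaults to the
#'   tree's `"splits"` attribute.
#' @return List of `paralog_group` objects (`member_ids`, `species`,
#'   `support`, `size`), ordered by decreasing support then size.
#' @export
find_paralog_groups <- function(tree, species_of, min_size = 4L,
                                min_support = 90,
                                splits = attr(tree, "splits")) {
  if (is.null(splits) || is.null(splits$support))
    stop("tree carries no bootstrap support; run bootstrap_support() first")
  taxa <- tree$tip.label
  miss <- setdiff(taxa, names(species_of))
  if (length(miss))
    stop("no species for leaves: ", paste(miss, collapse = ", "))
  ntip <- length(taxa)
  nodes <- ntip + seq_len(tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")

  cand <- list()
  for (k in seq_along(nodes)) {
    members <- taxa[desc[[k]]]
    if (length(members) < min_size || length(members) > ntip - 2L) next
    spp <- unique(species_of[members])
    if (length(spp) != 1L) next
    key <- .split_key(members, taxa)
    hit <- match(key, splits$key)
    supp <- if (is.na(hit)) NA_real_ else splits$support[hit]
    if (is.na(supp) || supp < min_support) next
    cand[[length(cand) + 1L]] <- structure(
      list(member_ids = sort(members), species = spp,
           support = supp, size = length(members)),
      class = "paralog_group"
    )
  }
  if (!length(cand)) return(list())
  # maximal, non-nested groups
  ord <- order(-vapply(cand, `[[`, 0L, "size"))
  kept <- list()
  for (i in ord) {
    nested <- any(vapply(kept, function(g)
      all(cand[[i]]$member_ids %in% g$member_ids), logical(1)))
    if (!nested) kept[[length(kept) + 1L]] <- cand[[i]]
  }
  kept[order(-vapply(kept, `[[`, 0, "support"),
             -vapply(kept, `[[`, 0L, "size"))]
}

#' @export
print.paralog_group <- function(x, ...) {
  cat(sprintf("<paralog_group> %s: %d genes, support %.1f%%\n  %s\n",
              x$species, x$size, x$support,
              paste(x$member_ids, collapse = ", ")))
  invisible(x)
}

#' Classify a joint two-species subtree
#'
#' Roots the tree by the outgroup and asks whether the focal gene set of
#' species A and its ortholog set of species B are each monophyletic.
#' Reciprocal monophyly (`species_specific`) implies duplication after the
#' species split; neither set monophyletic (`interleaved`) implies
#' duplication before it; one of the two is `unresolved`.
#'
#' @param tree A `phylo` tree containing all listed ids.
#' @param species_of Named species map for the leaves (used for reporting).
#' @param group_a Gene ids of the species-A paralog group.
#' @param orthologs_b Gene ids of the species-B ortholog set.
#' @param outgroup Outgroup leaf ids (non-empty, disjoint from both sets).
#'   If the outgroup is not monophyletic the tree is rooted at its most
#'   recent common ancestor, with a warning.
#' @param splits Optional support table from [bootstrap_support()] used to
#'   annotate the two defining clades.
#' @return A `cross_species_class` object with `verdict`
#'   (`species_specific` / `interleaved` / `unresolved`), per-set
#'   monophyly flags, and the bootstrap supports of the two defining
#'   clades (`NA` where unavailable).
#' @export
classify_cross_species <- function(tree, species_of, group_a, orthologs_b,
                                   outgroup, splits = attr(tree, "splits")) {
  taxa <- tree$tip.label
  miss <- setdiff(c(group_a, orthologs_b, outgroup), taxa)
  if (length(miss)) stop("ids not in tree: ", paste(miss, collapse = ", "))
  if (!length(outgroup)) stop("outgroup must be non-empty")
  if (length(intersect(outgroup, c(group_a, orthologs_b))))
    stop("outgroup overlaps the focal gene sets")

  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
    error = function(e) {
      warning("outgroup is not monophyletic; rooting at its most recent ",
              "common ancestor")
      mrca <- ape::getMRCA(tree, outgroup)
      tryCatch(ape::root(tree, node = mrca, resolve.root = TRUE),
               error = function(e2)
                 ape::root(tree, outgroup = outgroup[1],
                           resolve.root = TRUE))
    }
  )
  a_mono <- ape::is.monophyletic(rooted, group_a)
  b_mono <- ape::is.monophyletic(rooted, orthologs_b)
  verdict <- if (a_mono && b_mono) "species_specific"
             else if (!a_mono && !b_mono) "interleaved"
             else "unresolved"

  lookup <- function(ids) {
    if (is.null(splits) || is.null(splits$support)) return(NA_real_)
    hit <- match(.split_key(ids, taxa), splits$key)
    if (is.na(hit)) NA_real_ else splits$support[hit]
  }
  structure(
    list(verdict = verdict,
         a_monophyletic = a_mono, b_monophyletic = b_mono,
         support_a = lookup(group_a), support_b = lookup(orthologs_b),
         group_a = sort(group_a), orthologs_b = sort(orthologs_b),
         species_a = unname(unique(species_of[group_a])),
         species_b = unname(unique(species_of[orthologs_b]))),
    class = "cross_species_class"
  )
}

#' @export
print.cross_species_class <- function(x, ...) {
  cat(sprintf(
    "<cross_species_class> %s (A monophyletic: %s [%.1f], B monophyletic: %s [%.1f])\n",
    x$verdict, x$a_monophyletic, x$support_a, x$b_monophyletic, x$support_b))
  invisible(x)
}
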