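# End-to-end discovery pipeline: alignment -> NJ tree with bootstrap ->
# supported paralog groups -> cross-species classification -> RBH ->
# tandem arrays and synteny -> duplication history -> dN/dS + integrity.

#' Pipeline configuration
#'
#' Thresholds mirror the discovery procedure the package implements: at
#' least four paralogs under a >= 90% bootstrap edge, tandem arrays split
#' at 15 kb, and two ordered flanking anchors for a syntenic call.
#'
#' @param min_size Minimum paralog-group size.
#' @param min_support Minimum bootstrap percentage.
#' @param bootstrap_replicates Bootstrap replicates for the gene tree.
#' @param max_gap_kb Tandem-array gap threshold (kb).
#' @param flank,min_anchors Synteny-test parameters.
#' @param distance_model `"p_distance"` or `"poisson"`.
#' @param seed Integer seed controlling the bootstrap resampling.
#' @param outdir Optional output directory for TSV/JSON/newick artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_size = 4L, min_support = 90,
                            bootstrap_replicates = 1000L,
                            max_gap_kb = 15, flank = 3L, min_anchors = 2L,
                            distance_model = "p_distance", seed = 1L,
                            outdir = NULL) {
  if (min_size < 1L || min_support < 0 || bootstrap_replicates < 1L ||
      max_gap_kb <= 0 || flank < 1L || min_anchors < 1L)
    stop("pipeline thresholds must be positive")
  structure(list(min_size = as.integer(min_size), min_support = min_support,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 max_gap_kb = max_gap_kb, flank = as.integer(flank),
                 min_anchors = as.integer(min_anchors),
                 distance_model = distance_model, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Load a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `cds_tree.fasta`,
#'   `cds_<sp>.fasta` / `proteins_<sp>.fasta` / `genes_<sp>.tsv` per
#'   species, and optionally `truth.json`.
#' @return A dataset list usable by [run_pipeline()].
#' @export
read_dataset <- function(dir) {
  cds_tree <- read_fasta(file.path(dir, "cds_tree.fasta"))
  gt_files <- list.files(dir, "^genes_.*\\.tsv$", full.names = TRUE)
  if (!length(gt_files)) stop("no gene tables found in ", dir)
  gene_table <- do.call(rbind, lapply(gt_files, read_gene_table))
  species <- unique(gene_table$species)
  cds_all <- proteins <- character(0)
  for (sp in species) {
    cds_all <- c(cds_all, read_fasta(file.path(dir,
                                               sprintf("cds_%s.fasta", sp))))
    proteins <- c(proteins,
                  read_fasta(file.path(dir, sprintf("proteins_%s.fasta", sp))))
  }
  species_of <- setNames(
    gene_table$species[match(names(cds_all), gene_table$gene_id)],
    names(cds_all))
  meta_path <- file.path(dir, "truth.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  family_ids <- if (!is.null(meta)) meta$family_ids else NULL
  outgroup_ids <- if (!is.null(meta)) meta$outgroup_ids else character(0)
  if (is.null(family_ids)) {
    fam <- setdiff(names(cds_tree), outgroup_ids)
    family_ids <- split(fam, species_of[fam])
  }
  list(cds = cds_tree, proteins = proteins, cds_all = cds_all,
       gene_table = gene_table, species_of = species_of,
       family_ids = family_ids, outgroup_ids = outgroup_ids,
       truth = if (!is.null(meta)) meta$truth else NULL)
}

#' Run the full discovery pipeline
#'
#' Stages: nucleotide progressive alignment of the family + outgroup CDSs;
#' NJ tree with bootstrap support; supported same-species paralog groups;
#' cross-species reciprocal-monophyly classification (rooted by the
#' outgroup); reciprocal-best-hit orthologs over both proteomes; tandem
#' arrays; per-array flanking-anchor synteny; duplication-history call;
#' NG86 dN/dS among intact family members; per-gene integrity reports.
#' The report is a pure function of (dataset, config).
#'
#' @param dataset A `simulated_dataset` (from [simulate_family()]) or a
#'   dataset list from [read_dataset()].
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list (tree, groups, cross-species verdicts,
#'   rbh, arrays, synteny reports, history call, dnds, integrity,
#'   config).
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config")
  need <- c("cds", "proteins", "gene_table", "species_of", "family_ids")
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    stop("dataset is missing components: ", paste(miss, collapse = ", "))
  if (!length(dataset$cds)) stop("stage input: no CDS sequences")
  species <- sort(unique(dataset$gene_table$species))
  two_species <- length(species) >= 2L
  timings <- c()
  tick <- function(name, t0) {
    timings[name] <<- round(as.numeric(Sys.time()) - t0, 2)
  }

  t0 <- as.numeric(Sys.time())
  msa <- progressive_msa(dataset$cds, scoring_params("NUC"))
  tick("msa", t0)

  t0 <- as.numeric(Sys.time())
  tree <- bootstrap_support(msa, model = config$distance_model,
                            replicates = config$bootstrap_replicates,
                            seed = config$seed)
  splits <- attr(tree, "splits")
  tick("tree", t0)

  rooted <- if (length(dataset$outgroup_ids) &&
                all(dataset$outgroup_ids %in% tree$tip.label)) {
    tryCatch(ape::root(tree, outgroup = dataset$outgroup_ids,
                       resolve.root = TRUE),
             error = function(e) ape::root(
               tree, node = ape::getMRCA(tree, dataset$outgroup_ids),
               resolve.root = TRUE))
  } else {
    phangorn::midpoint(tree)
  }

  # outgroup genes are never family-group candidates, whatever their genome
  grouping_species <- dataset$species_of
  grouping_species[dataset$outgroup_ids] <- ".outgroup"
  groups <- find_paralog_groups(rooted, grouping_species,
                                min_size = config$min_size,
                                min_support = config$min_support,
                                splits = splits)
  groups <- Filter(function(g) g$species != ".outgroup", groups)

  cross <- list()
  if (two_species && length(groups) && length(dataset$outgroup_ids)) {
    for (g in groups) {
      other <- setdiff(species, g$species)[1]
      orth <- intersect(dataset$family_ids[[other]], tree$tip.label)
      if (!length(orth)) next
      cross[[paste(g$member_ids, collapse = ",")]] <-
        classify_cross_species(tree, dataset$species_of, g$member_ids,
                               orth, dataset$outgroup_ids, splits = splits)
    }
  }

  rbh <- NULL
  arrays <- list()
  syn_reports <- list(A = list(), B = list())
  history <- NULL
  if (two_species) {
    spA <- species[1]
    spB <- species[2]
    t0 <- as.numeric(Sys.time())
    prots <- dataset$proteins[nchar(dataset$proteins) > 0]
    rbh <- reciprocal_best_hits(
      prots[names(prots)[dataset$species_of[names(prots)] == spA]],
      prots[names(prots)[dataset$species_of[names(prots)] == spB]])
    tick("rbh", t0)

    fam_a <- dataset$family_ids[[spA]]
    fam_b <- dataset$family_ids[[spB]]
    tab_a <- dataset$gene_table[dataset$gene_table$species == spA, ]
    tab_b <- dataset$gene_table[dataset$gene_table$species == spB, ]
    arrays <- tandem_arrays(dataset$gene_table, c(fam_a, fam_b),
                            max_gap_kb = config$max_gap_kb)
    rbh_rev <- data.frame(id_a = rbh$id_b, id_b = rbh$id_a,
                          score = rbh$score)
    for (arr in arrays) {
      rep <- if (arr$species == spA) {
        synteny_test(arr$member_ids, rbh, tab_a, tab_b, fam_a, fam_b,
                     flank = config$flank, min_anchors = config$min_anchors)
      } else {
        synteny_test(arr$member_ids, rbh_rev, tab_b, tab_a, fam_b, fam_a,
                     flank = config$flank, min_anchors = config$min_anchors)
      }
      key <- if (arr$species == spA) "A" else "B"
      syn_reports[[key]][[length(syn_reports[[key]]) + 1L]] <- rep
    }
    cross_top <- if (length(cross)) cross[[1]]$verdict else "unresolved"
    history <- duplication_history(cross_top, syn_reports$A, syn_reports$B)
  }

  # integrity + dN/dS among family genes
  fam_all <- intersect(unlist(dataset$family_ids), names(dataset$cds))
  screen_intact <- fam_all[vapply(fam_all, function(id) {
    s <- dataset$cds[[id]]
    nchar(s) %% 3L == 0L &&
      !suppressWarnings(translate_cds(s))$premature_stop
  }, logical(1))]
  integrity <- list()
  if (length(screen_intact) >= 2L) {
    consensus <- family_consensus(dataset$cds[screen_intact])
    for (id in fam_all) {
      rec <- list(id = id, cds = dataset$cds[[id]],
                  protein = dataset$proteins[[id]],
                  cleavage_index = NA_integer_)
      integrity[[id]] <- integrity_report(rec, consensus)
    }
  }
  verdicts <- vapply(integrity, `[[`, character(1), "verdict")
  intact <- names(verdicts)[verdicts == "intact"]
  dnds <- NULL
  if (length(intact) >= 2L) {
    prot <- setNames(vapply(dataset$cds[intact], function(s)
      suppressWarnings(.translate_orf(s)), character(1)), intact)
    aa_msa <- progressive_msa(prot, scoring_params("BLOSUM62"))
    codon_msa <- codon_backtranslate(aa_msa, dataset$cds[intact])
    dnds <- dnds_matrix(codon_msa)
  }

  report <- structure(
    list(tree = tree, rooted_tree = rooted, splits = splits,
         groups = groups, cross_species = cross, rbh = rbh,
         arrays = arrays, synteny = syn_reports, history = history,
         dnds = dnds, integrity = integrity,
         config = config, timings = timings,
         n_genes = length(dataset$cds), species = species),
    class = "pipeline_report"
  )
  if (!is.null(config$outdir)) .write_report(report, config$outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d genes, %d paralog group(s)\n",
              x$n_genes, length(x$groups)))
  for (i in seq_along(x$groups)) {
    g <- x$groups[[i]]
    key <- paste(g$member_ids, collapse = ",")
    verdict <- if (!is.null(x$cross_species[[key]]))
      x$cross_species[[key]]$verdict else "-"
    cat(sprintf("  group %d [%s] n=%d support=%.1f cross-species: %s\n",
                i, g$species, g$size, g$support, verdict))
  }
  if (!is.null(x$history))
    cat(sprintf("  history: %s\n", x$history$verdict))
  lof <- sum(vapply(x$integrity, `[[`, character(1), "verdict") ==
               "putative_loss_of_function")
  cat(sprintf("  integrity: %d putative loss-of-function of %d family genes\n",
              lof, length(x$integrity)))
  invisible(x)
}

.write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_newick(report$tree, file.path(outdir, "tree.nwk"))
  if (length(report$groups)) {
    gr <- do.call(rbind, lapply(seq_along(report$groups), function(i) {
      g <- report$groups[[i]]
      data.frame(group = i, species = g$species, size = g$size,
                 support = g$support,
                 members = paste(g$member_ids, collapse = ","))
    }))
    write.table(gr, file.path(outdir, "paralog_groups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (length(report$arrays)) {
    ar <- do.call(rbind, lapply(report$arrays, function(a)
      data.frame(species = a$species, scaffold = a$scaffold,
                 size = length(a$member_ids), span = a$span,
                 members = paste(a$member_ids, collapse = ","))))
    write.table(ar, file.path(outdir, "tandem_arrays.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$dnds)) {
    write.table(report$dnds$pairs, file.path(outdir, "dnds_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(report$integrity)) {
    ir <- do.call(rbind, lapply(report$integrity, function(r)
      data.frame(gene_id = r$id, verdict = r$verdict,
                 frameshift = r$frameshift,
                 frameshift_position = r$frameshift_position,
                 premature_stop = r$premature_stop,
                 cysteine_loss = r$cysteine_loss,
                 cxc_terminal = r$cxc_terminal)))
    write.table(ir, file.path(outdir, "integrity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$history)) {
    jsonlite::write_json(
      list(verdict = report$history$verdict,
           cross_species = report$history$cross_species,
           evidence = report$history$evidence),
      file.path(outdir, "history.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(outdir)
}
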