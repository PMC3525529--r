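# Gene-family evolution simulator. Two species diverge from a common
# ancestor; family genes duplicate within lineages (the first duplication
# founds a new tandem locus, later ones expand it locally), sequences
# evolve under a codon accept/reject scheme with tunable dN/dS, copies can
# pseudogenize, and slowly evolving single-copy flanking genes provide
# clean orthology/synteny anchors. Every emitted dataset carries its
# ground truth.

#' Simulation configuration
#'
#' Defaults describe the study scenario the package targets: a single
#' ancestral defensin-like gene, five post-speciation duplications in
#' species A (one founding a new locus, four expanding it in tandem within
#' 15 kb) and nine in species B, moderate divergence, and conserved
#' flanking anchor genes.
#'
#' @param ancestral_family_size Family copies present before speciation.
#' @param root_sequence_length Family CDS length in codons.
#' @param root_branch Expected substitutions/site from the family root to
#'   speciation.
#' @param species_branch Expected substitutions/site from speciation to
#'   the present, per species.
#' @param dup_events Named integer vector `c(A = , B = )` of
#'   post-speciation duplications per lineage.
#' @param dup_time_range Window of duplication times as fractions of the
#'   species branch (0 = speciation, 1 = present); the default places the
#'   expansion in the recent half of each lineage, as implied by the high
#'   within-species identities of recently amplified tandem families.
#' @param tandem_spacing_kb Range (kb) of intergenic spacing inside a
#'   tandem array; default uniform on 0.5-15.
#' @param flank_spacing_kb Range (kb) of spacing between anchor genes.
#' @param omega_family,omega_flank dN/dS acceptance ratios for family and
#'   flanking genes.
#' @param pseudogenization_prob Probability that a duplicated copy
#'   pseudogenizes (frameshift or premature stop, chosen at random).
#' @param forced_pseudogene `NULL`, or a list like
#'   `list(lineage = "A", type = "frameshift", position = 17)` applied to
#'   the youngest tandem copy of that lineage.
#' @param flanking_genes Anchor genes per side of each locus.
#' @param flank_length Anchor CDS length in codons.
#' @param outgroup_n Outgroup genes (placed in genome A, diverged before
#'   the family root).
#' @param outgroup_branch Extra divergence of the outgroup lineage.
#' @return A `sim_config` list.
#' @export
sim_config <- function(ancestral_family_size = 1L,
                       root_sequence_length = 100L,
                       root_branch = 0.05,
                       species_branch = 0.18,
                       dup_events = c(A = 5L, B = 9L),
                       dup_time_range = c(0.45, 0.9),
                       tandem_spacing_kb = c(0.5, 15),
                       flank_spacing_kb = c(1, 5),
                       omega_family = 0.5,
                       omega_flank = 0.1,
                       pseudogenization_prob = 0,
                       forced_pseudogene = NULL,
                       flanking_genes = 3L,
                       flank_length = 120L,
                       outgroup_n = 2L,
                       outgroup_branch = 0.25) {
  cfg <- list(ancestral_family_size = as.integer(ancestral_family_size),
              root_sequence_length = as.integer(root_sequence_length),
              root_branch = root_branch, species_branch = species_branch,
              dup_events = dup_events, dup_time_range = dup_time_range,
              tandem_spacing_kb = tandem_spacing_kb,
              flank_spacing_kb = flank_spacing_kb,
              omega_family = omega_family, omega_flank = omega_flank,
              pseudogenization_prob = pseudogenization_prob,
              forced_pseudogene = forced_pseudogene,
              flanking_genes = as.integer(flanking_genes),
              flank_length = as.integer(flank_length),
              outgroup_n = as.integer(outgroup_n),
              outgroup_branch = outgroup_branch)
  with(cfg, {
    if (ancestral_family_size < 1L) stop("ancestral_family_size must be >= 1")
    if (root_sequence_length < 10L) stop("root_sequence_length too short")
    if (any(c(root_branch, species_branch, outgroup_branch) < 0))
      stop("branch lengths must be >= 0")
    if (omega_family <= 0 || omega_flank <= 0) stop("omega must be > 0")
    if (any(dup_events < 0)) stop("duplication counts must be >= 0")
    if (ancestral_family_size == 0L && any(dup_events > 0L))
      stop("duplication without a family")
  })
  structure(cfg, class = "sim_config")
}

#' The planted species-specific cluster preset
#'
#' One ancestral gene; species A gains a new-locus copy plus four tandem
#' duplicates (six genes, the youngest carrying a 1-bp frameshift deletion
#' at nucleotide 17), species B gains nine copies at a different locus
#' (ten genes). The expected pipeline outcome is a species-specific
#' cluster with an ancestral-copy-plus-lineage-specific-expansion history.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
crp810_preset <- function(...) {
  args <- list(...)
  base <- list(forced_pseudogene = list(lineage = "A", type = "frameshift",
                                        position = 17L))
  do.call(sim_config, utils::modifyList(base, args))
}

# random CDS with no in-frame stop codons; optionally excluding amino
# acids (the family root excludes background cysteines so that the
# planted scaffold is the family's cysteine complement)
.random_cds <- function(n_codons, exclude_aa = character(0)) {
  gc <- .genetic_code()
  pool <- names(gc)[gc != "*" & !(gc %in% exclude_aa)]
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# Codon accept/reject evolution: proposals arrive at rate t per site,
# mutate uniformly to one of the 3 other bases; stop-creating proposals
# are rejected; synonymous vs nonsynonymous proposals are accepted with
# probabilities (1, omega) for omega <= 1 and (1/omega, 1) for omega > 1,
# so the accepted nonsynonymous:synonymous rate ratio is always omega.
# Codons listed in `protected` (the conserved cysteine scaffold) accept
# nonsynonymous changes with probability `p_protected` instead.
.evolve_cds <- function(cds, t, omega, protected = integer(0),
                        p_protected = 0.02) {
  if (t <= 0) return(cds)
  bases <- strsplit(cds, "")[[1]]
  L <- length(bases)
  n <- rpois(1, t * L)
  if (n == 0L) return(cds)
  p_syn <- min(1, 1 / omega)
  p_non <- min(1, omega)
  sites <- sample.int(L, n, replace = TRUE)
  gc <- .genetic_code()
  for (i in sites) {
    old <- bases[i]
    new <- sample(setdiff(.BASES, old), 1L)
    c0 <- (i - 1L) %/% 3L
    cod <- paste(bases[(c0 * 3L + 1L):(c0 * 3L + 3L)], collapse = "")
    ncod <- cod
    substr(ncod, i - c0 * 3L, i - c0 * 3L) <- new
    if (gc[[ncod]] == "*") next # keep the frame free of stops
    accept <- if (gc[[ncod]] == gc[[cod]]) p_syn
              else if ((c0 + 1L) %in% protected) p_protected
              else p_non
    if (accept >= 1 || runif(1) < accept) bases[i] <- new
  }
  paste(bases, collapse = "")
}

#' Simulate a two-species gene family with ground truth
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical `(config, seed)` pairs give
#'   identical datasets.
#' @return A `simulated_dataset` list: `cds` (family + outgroup genes),
#'   `proteins` (all genes, both species), `cds_all`, `gene_table`
#'   (both species; write per species with [write_dataset()]),
#'   `species_of`, `family_ids` (per species), `outgroup_ids`, `truth`
#'   (true tree in newick, clusters, arrays, history verdict, pseudogene
#'   list, per-class omega), `config`, `seed`.
#' @export
simulate_family <- function(config = sim_config(), seed = 1L) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  set.seed(seed)
  cfg <- config
  Lc <- cfg$root_sequence_length

  anc_root <- .random_cds(Lc, exclude_aa = "C")
  # plant the DEFL cysteine scaffold: six cysteine codons in the mature
  # region, the last two forming the C-terminal CXC motif; these codons
  # evolve under strong purifying selection
  signal_codons <- min(25L, Lc %/% 4L)
  cys_codons <- sort(unique(c(
    round(seq(signal_codons + 2L, Lc - 6L, length.out = 4)),
    Lc - 2L, Lc)))
  for (cp in cys_codons) substr(anc_root, cp * 3L - 2L, cp * 3L) <- "TGT"
  fam_evolve <- function(s, t, omega = cfg$omega_family)
    .evolve_cds(s, t, omega, protected = cys_codons)

  # ancestral family copies (jittered from a common family root)
  anc <- lapply(seq_len(cfg$ancestral_family_size), function(k)
    fam_evolve(anc_root, if (cfg$ancestral_family_size > 1) 0.05 else 0))

  # outgroup: diverged before the family root, genome A residents
  outgroup <- list()
  if (cfg$outgroup_n > 0L) {
    for (j in seq_len(cfg$outgroup_n)) {
      outgroup[[sprintf("A_out%d", j)]] <-
        fam_evolve(anc_root, cfg$outgroup_branch + 0.05 * (j - 1))
    }
  }

  # evolve each ancestral copy to the speciation point
  at_spec <- lapply(anc, fam_evolve, t = cfg$root_branch)

  # per-lineage birth-death-free duplication process
  lineage <- function(species) {
    tb <- cfg$species_branch
    ndup <- as.integer(cfg$dup_events[[species]])
    genes <- list()
    for (k in seq_along(at_spec)) {
      id <- sprintf("%s_fam%d", species, k)
      genes[[id]] <- list(id = id, seq = at_spec[[k]], t = 0,
                          locus = "alpha", parent = NA_character_,
                          birth = 0)
    }
    events <- if (ndup > 0L)
      sort(runif(ndup, cfg$dup_time_range[1], cfg$dup_time_range[2]) * tb)
    else numeric(0)
    expansion_locus <- if (species == "A") "beta" else "gamma"
    for (e in seq_along(events)) {
      te <- events[e]
      for (id in names(genes)) {
        g <- genes[[id]]
        genes[[id]]$seq <- fam_evolve(g$seq, te - g$t)
        genes[[id]]$t <- te
      }
      src <- if (e == 1L) names(genes)[1] else {
        in_loc <- names(genes)[vapply(genes, function(g)
          g$locus == expansion_locus, logical(1))]
        sample(in_loc, 1L)
      }
      nid <- sprintf("%s_fam%d", species, length(genes) + 1L)
      genes[[nid]] <- list(id = nid, seq = genes[[src]]$seq, t = te,
                           locus = expansion_locus, parent = src,
                           birth = te)
      attr(genes[[nid]], "birth_order") <- e
    }
    for (id in names(genes)) {
      g <- genes[[id]]
      genes[[id]]$seq <- fam_evolve(g$seq, tb - g$t)
      genes[[id]]$t <- tb
    }
    list(genes = genes, events = data.frame(
      time = events,
      source = vapply(seq_along(events), function(e)
        genes[[cfg$ancestral_family_size + e]]$parent, character(1)),
      new_id = names(genes)[cfg$ancestral_family_size + seq_along(events)],
      stringsAsFactors = FALSE))
  }
  linA <- lineage("A")
  linB <- lineage("B")

  # pseudogenization
  pseudogenes <- list()
  apply_pseudo <- function(lin, species) {
    ids <- names(lin$genes)
    dup_ids <- ids[vapply(lin$genes, function(g) !is.na(g$parent),
                          logical(1))]
    hit <- character(0)
    if (cfg$pseudogenization_prob > 0 && length(dup_ids)) {
      hit <- dup_ids[runif(length(dup_ids)) < cfg$pseudogenization_prob]
    }
    fp <- cfg$forced_pseudogene
    if (!is.null(fp) && identical(fp$lineage, species) && length(dup_ids)) {
      hit <- union(hit, dup_ids[length(dup_ids)]) # youngest copy
    }
    for (id in hit) {
      s <- lin$genes[[id]]$seq
      forced_here <- !is.null(fp) && identical(fp$lineage, species) &&
        id == dup_ids[length(dup_ids)]
      type <- if (forced_here) fp$type
              else sample(c("frameshift", "premature_stop"), 1L)
      if (type == "frameshift") {
        pos <- if (forced_here && !is.null(fp$position)) fp$position
               else sample(10:(nchar(s) - 20L), 1L)
        s <- paste0(substr(s, 1L, pos - 1L), substr(s, pos + 1L, nchar(s)))
        pseudogenes[[id]] <<- list(id = id, type = "frameshift",
                                   position = as.integer(pos))
      } else {
        cidx <- sample(5:(nchar(s) %/% 3L - 5L), 1L)
        substr(s, cidx * 3L - 2L, cidx * 3L) <- "TAA"
        pseudogenes[[id]] <<- list(id = id, type = "premature_stop",
                                   position = as.integer(cidx))
      }
      lin$genes[[id]]$seq <- s
    }
    lin
  }
  linA <- apply_pseudo(linA, "A")
  linB <- apply_pseudo(linB, "B")

  # flanking anchor genes: slow, single copy, 1:1 across species.
  # Loci: alpha (family in both), beta (family in A only), gamma (family
  # in B only); all three flank sets exist in both genomes.
  flanks <- list()
  for (locus in c("alpha", "beta", "gamma")) {
    for (side in c("L", "R")) {
      for (j in seq_len(cfg$flanking_genes)) {
        anc_f <- .random_cds(cfg$flank_length)
        for (sp in c("A", "B")) {
          id <- sprintf("%s_flk_%s_%s%d", sp, locus, side, j)
          flanks[[id]] <- list(id = id, species = sp, locus = locus,
                               side = side, rank = j,
                               seq = .evolve_cds(anc_f, cfg$species_branch,
                                                 cfg$omega_flank))
        }
      }
    }
  }

  # genome layout
  sp_kb <- function(rng) round(runif(1, rng[1], rng[2]) * 1000)
  layout_species <- function(species, lin) {
    scaf <- paste0("chr", species, "1")
    rows <- list()
    pos <- 1L
    add_gene <- function(id, len, gap) {
      start <- pos + gap
      rows[[length(rows) + 1L]] <<- data.frame(
        species = species, gene_id = id, scaffold = scaf,
        start = start, end = start + len - 1L,
        strand = if (length(rows) %% 2L == 0L) "+" else "-",
        stringsAsFactors = FALSE)
      pos <<- start + len - 1L
    }
    flank_ids <- function(locus, side) {
      ids <- sprintf("%s_flk_%s_%s%d", species, locus, side,
                     seq_len(cfg$flanking_genes))
      if (side == "L") rev(ids) else ids
    }
    fam_at <- function(locus) {
      ids <- names(lin$genes)[vapply(lin$genes, function(g)
        g$locus == locus, logical(1))]
      ids[order(vapply(ids, function(i) lin$genes[[i]]$birth, 0))]
    }
    if (species == "A" && length(outgroup)) {
      for (id in names(outgroup))
        add_gene(id, nchar(outgroup[[id]]), sp_kb(cfg$flank_spacing_kb))
      pos <- pos + 100000L
    }
    for (locus in c("alpha", "beta", "gamma")) {
      for (id in flank_ids(locus, "L"))
        add_gene(id, nchar(flanks[[id]]$seq), sp_kb(cfg$flank_spacing_kb))
      fam <- fam_at(locus)
      for (k in seq_along(fam)) {
        gap <- if (k == 1L) sp_kb(cfg$flank_spacing_kb)
               else sp_kb(cfg$tandem_spacing_kb)
        add_gene(fam[k], nchar(lin$genes[[fam[k]]]$seq), gap)
      }
      for (id in flank_ids(locus, "R"))
        add_gene(id, nchar(flanks[[id]]$seq), sp_kb(cfg$flank_spacing_kb))
      pos <- pos + 100000L
    }
    do.call(rbind, rows)
  }
  tabA <- layout_species("A", linA)
  tabB <- layout_species("B", linB)
  gene_table <- rbind(tabA, tabB)

  # assemble sequence sets
  fam_seqs <- c(
    setNames(lapply(linA$genes, `[[`, "seq"), names(linA$genes)),
    setNames(lapply(linB$genes, `[[`, "seq"), names(linB$genes))
  )
  fam_seqs <- unlist(fam_seqs)
  out_seqs <- unlist(outgroup)
  flk_seqs <- vapply(flanks, `[[`, character(1), "seq")
  cds_tree <- c(fam_seqs, out_seqs) # tree-stage input
  cds_all <- c(fam_seqs, out_seqs, flk_seqs)
  proteins <- vapply(cds_all, function(s)
    suppressWarnings(.translate_orf(s)), character(1))

  species_of <- setNames(substr(names(cds_all), 1L, 1L), names(cds_all))

  # truth
  newick <- .true_family_newick(cfg, linA, linB, names(outgroup))
  family_ids <- list(A = names(linA$genes), B = names(linB$genes))
  # true arrays = family genes grouped by the locus they were placed at
  true_arrays <- list()
  for (lin in list(A = linA, B = linB)) {
    sp <- substr(names(lin$genes)[1], 1L, 1L)
    loci <- vapply(lin$genes, `[[`, character(1), "locus")
    for (loc in unique(loci)) {
      ids <- names(loci)[loci == loc]
      gt <- gene_table[match(ids, gene_table$gene_id), , drop = FALSE]
      true_arrays[[length(true_arrays) + 1L]] <- list(
        species = sp, scaffold = gt$scaffold[1], locus = loc,
        member_ids = ids[order(gt$start)],
        span = max(gt$end) - min(gt$start) + 1L)
    }
  }
  cross_truth <- if (cfg$ancestral_family_size == 1L) "species_specific"
                 else "interleaved"
  history_truth <-
    if (cfg$ancestral_family_size == 1L && all(cfg$dup_events >= 1L))
      "ancestral_copy_plus_lineage_specific_expansion"
    else if (all(cfg$dup_events == 0L)) "shared_ancestral_array"
    else "unresolved"

  structure(
    list(cds = cds_tree, proteins = proteins, cds_all = cds_all,
         gene_table = gene_table, species_of = species_of,
         family_ids = family_ids, outgroup_ids = names(outgroup),
         truth = list(
           tree_newick = newick,
           species_of = species_of[c(names(fam_seqs), names(out_seqs))],
           clusters = lapply(family_ids, sort),
           arrays = true_arrays,
           cross_species = cross_truth,
           history = history_truth,
           pseudogenes = pseudogenes,
           signal_codons = signal_codons,
           cys_codons = cys_codons,
           omega = list(family = cfg$omega_family,
                        flank = cfg$omega_flank)),
         config = cfg, seed = seed),
    class = "simulated_dataset"
  )
}

# true gene tree in newick (branch lengths in nominal proposal units)
.true_family_newick <- function(cfg, linA, linB, outgroup_ids) {
  tb <- cfg$species_branch
  grow <- function(lin, id, t0) {
    ev <- lin$events[lin$events$source == id & lin$events$time > t0, ,
                     drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    if (nrow(ev) == 0L) return(sprintf("%s:%g", id, tb - t0))
    e <- ev[1L, ]
    sprintf("(%s,%s):%g",
            grow(lin, id, e$time), grow(lin, e$new_id, e$time),
            e$time - t0)
  }
  subtrees <- vapply(seq_len(cfg$ancestral_family_size), function(k) {
    a <- grow(linA, sprintf("A_fam%d", k), 0)
    b <- grow(linB, sprintf("B_fam%d", k), 0)
    sprintf("(%s,%s):%g", a, b, cfg$root_branch)
  }, character(1))
  fam <- if (length(subtrees) == 1L) subtrees
         else sprintf("(%s):%g", paste(subtrees, collapse = ","), 0.02)
  if (length(outgroup_ids)) {
    og <- paste(sprintf("%s:%g", outgroup_ids, cfg$outgroup_branch),
                collapse = ",")
    sprintf("(%s,%s);", fam, og)
  } else {
    sprintf("(%s);", fam)
  }
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> seed %d: %d family genes (A: %d, B: %d), %d outgroup, %d genes total\n",
    x$seed, length(unlist(x$family_ids)), length(x$family_ids$A),
    length(x$family_ids$B), length(x$outgroup_ids), nrow(x$gene_table)))
  invisible(x)
}

#' Write / read a simulated dataset as plain-text files
#'
#' Writes per-species CDS and protein FASTA, per-species gene tables, the
#' tree-stage CDS FASTA, and the ground truth as JSON.
#'
#' @param dataset A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (`read_dataset` returns the dataset list).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$cds, file.path(dir, "cds_tree.fasta"))
  for (sp in unique(dataset$gene_table$species)) {
    sel <- names(dataset$cds_all)[dataset$species_of == sp]
    write_fasta(dataset$cds_all[sel],
                file.path(dir, sprintf("cds_%s.fasta", sp)))
    write_fasta(dataset$proteins[sel],
                file.path(dir, sprintf("proteins_%s.fasta", sp)))
    write_gene_table(
      dataset$gene_table[dataset$gene_table$species == sp, ],
      file.path(dir, sprintf("genes_%s.tsv", sp)))
  }
  meta <- dataset[c("family_ids", "outgroup_ids", "truth", "seed")]
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Recovery metrics against simulation truth
#'
#' Exact-set matching for paralog groups and tandem arrays, verdict
#' equality for the history call.
#'
#' @param inferred List with `groups` (list of id vectors), `arrays`
#'   (list of id vectors) and/or `history` (verdict string).
#' @param truth The `truth` element of a `simulated_dataset`.
#' @return List of per-class metrics: `sensitivity`, `precision` for
#'   groups and arrays (`NA` where a class was not supplied), and
#'   `history_match`.
#' @export
score_recovery <- function(inferred, truth) {
  set_metrics <- function(inf, tru) {
    if (is.null(inf)) return(c(sensitivity = NA_real_, precision = NA_real_))
    key <- function(x) paste(sort(x), collapse = "\r")
    ik <- vapply(inf, key, character(1))
    tk <- vapply(tru, key, character(1))
    if (length(setdiff(unlist(inf), unlist(tru))) &&
        !length(intersect(unlist(inf), unlist(tru))))
      stop("inferred and truth id spaces do not overlap")
    c(sensitivity = if (length(tk)) sum(tk %in% ik) / length(tk) else NA,
      precision = if (length(ik)) sum(ik %in% tk) / length(ik) else NA)
  }
  truth_groups <- unname(truth$clusters)
  truth_arrays <- lapply(truth$arrays, `[[`, "member_ids")
  list(
    groups = set_metrics(inferred$groups, truth_groups),
    arrays = set_metrics(inferred$arrays, truth_arrays),
    history_match = if (is.null(inferred$history)) NA
                    else identical(inferred$history, truth$history)
  )
}

#' Simulate an ingroup polymorphism panel plus outgroup for MK testing
#'
#' The outgroup and the ingroup ancestor each evolve `t_div` from the
#' common ancestor (divergence); the panel then evolves as `n_ingroup`
#' independent tips of a star genealogy of depth `t_poly` (polymorphism).
#'
#' @param n_ingroup Panel size (>= 2).
#' @param n_codons CDS length in codons.
#' @param t_div Divergence branch length, substitutions/site, each side.
#' @param t_poly Star-genealogy tip depth.
#' @param omega_div,omega_poly dN/dS on the divergence branches and
#'   within the panel.
#' @param seed Integer seed.
#' @return List with `ingroup` (named vector), `outgroup` (string) and
#'   the generating parameters.
#' @export
simulate_mk_panel <- function(n_ingroup = 8L, n_codons = 500L,
                              t_div = 0.03, t_poly = 0.01,
                              omega_div = 1, omega_poly = 1, seed = 1L) {
  if (n_ingroup < 2L) stop("n_ingroup must be >= 2")
  set.seed(seed)
  anc <- .random_cds(n_codons)
  outg <- .evolve_cds(anc, t_div, omega_div)
  in_anc <- .evolve_cds(anc, t_div, omega_div)
  ing <- vapply(seq_len(n_ingroup), function(i)
    .evolve_cds(in_anc, t_poly, omega_poly), character(1))
  names(ing) <- sprintf("in%d", seq_len(n_ingroup))
  list(ingroup = ing, outgroup = outg,
       params = list(n_ingroup = n_ingroup, n_codons = n_codons,
                     t_div = t_div, t_poly = t_poly,
                     omega_div = omega_div, omega_poly = omega_poly,
                     seed = seed))
}
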