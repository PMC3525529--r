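test_that("simulation is reproducible: same config and seed, identical output", {
  cfg <- crp810_preset()
  d1 <- simulate_family(cfg, seed = 5)
  d2 <- simulate_family(cfg, seed = 5)
  expect_identical(d1$cds_all, d2$cds_all)
  expect_identical(d1$gene_table, d2$gene_table)
  expect_identical(d1$truth$tree_newick, d2$truth$tree_newick)

  d3 <- simulate_family(cfg, seed = 6)
  expect_false(identical(d1$cds_all, d3$cds_all))
})

test_that("without duplications both species keep the ancestral family size", {
  ds <- simulate_family(sim_config(ancestral_family_size = 2,
                                   dup_events = c(A = 0, B = 0)), seed = 2)
  expect_equal(length(ds$family_ids$A), 2L)
  expect_equal(length(ds$family_ids$B), 2L)
  expect_equal(ds$truth$history, "shared_ancestral_array")
})

test_that("emitted CDSs are stop-free unless listed as pseudogenes", {
  ds <- simulate_family(crp810_preset(), seed = 9)
  pseudo <- names(ds$truth$pseudogenes)
  for (id in names(ds$cds_all)) {
    s <- ds$cds_all[[id]]
    if (id %in% pseudo) next
    expect_equal(nchar(s) %% 3, 0)
    expect_false(translate_cds(s)$premature_stop)
  }
  expect_true(length(pseudo) >= 1)
})

test_that("simulator pseudogenes are classified as loss of function", {
  ds <- simulate_family(crp810_preset(), seed = 12)
  pseudo <- names(ds$truth$pseudogenes)
  intact_a <- setdiff(ds$family_ids$A, pseudo)
  cons <- family_consensus(ds$cds[intact_a])
  for (id in pseudo) {
    rep <- integrity_report(list(id = id, cds = ds$cds[[id]],
                                 protein = NULL, cleavage_index = NA), cons)
    expect_equal(rep$verdict, "putative_loss_of_function")
  }
  # the forced frameshift sits at nucleotide 17, like the family pseudogene
  fs <- ds$truth$pseudogenes[[1]]
  expect_equal(fs$type, "frameshift")
  expect_equal(fs$position, 17L)
})

test_that("the true gene tree parses and matches the emitted gene set", {
  ds <- simulate_family(crp810_preset(), seed = 4)
  tr <- ape::read.tree(text = ds$truth$tree_newick)
  expect_setequal(tr$tip.label, names(ds$cds))
  # in the planted scenario each species' family is monophyletic in truth
  expect_true(ape::is.monophyletic(tr, ds$family_ids$A))
  expect_true(ape::is.monophyletic(tr, ds$family_ids$B))
})

test_that("neutral simulation yields unbiased NG86 omega estimates", {
  set.seed(90)
  om <- om02 <- numeric(30)
  for (r in 1:30) {
    anc <- random_cds_fixture(400)
    a <- deflevol:::.evolve_cds(anc, 0.15, 1)
    b <- deflevol:::.evolve_cds(anc, 0.15, 1)
    om[r] <- ng86_pairwise(a, b)$omega
    a2 <- deflevol:::.evolve_cds(anc, 0.15, 0.2)
    b2 <- deflevol:::.evolve_cds(anc, 0.15, 0.2)
    om02[r] <- ng86_pairwise(a2, b2)$omega
  }
  expect_gt(mean(om), 0.85)
  expect_lt(mean(om), 1.18)
  # purifying selection is recovered as a clearly lower estimate
  expect_lt(mean(om02), 0.5)
})

test_that("recovery metrics score exact set matches", {
  truth <- list(clusters = list(A = c("a1", "a2"), B = c("b1", "b2")),
                arrays = list(list(member_ids = c("a1", "a2"))),
                history = "shared_ancestral_array")
  perfect <- score_recovery(
    list(groups = list(c("a1", "a2"), c("b1", "b2")),
         arrays = list(c("a2", "a1")), history = "shared_ancestral_array"),
    truth)
  expect_equal(unname(perfect$groups), c(1, 1))
  expect_equal(unname(perfect$arrays), c(1, 1))
  expect_true(perfect$history_match)

  nothing <- score_recovery(list(groups = list(), history = "unresolved"),
                            truth)
  expect_equal(unname(nothing$groups[["sensitivity"]]), 0)
  expect_false(nothing$history_match)

  half <- score_recovery(list(groups = list(c("a1", "a2"))), truth)
  expect_equal(unname(half$groups), c(0.5, 1))
})

test_that("datasets round-trip through plain-text files", {
  ds <- simulate_family(crp810_preset(), seed = 8)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$cds, ds$cds)
  expect_equal(sort(names(back$proteins)), sort(names(ds$proteins)))
  expect_equal(back$gene_table[order(back$gene_table$gene_id), ],
               ds$gene_table[order(ds$gene_table$gene_id), ],
               ignore_attr = TRUE)
  expect_setequal(unname(unlist(back$family_ids)),
                  unname(unlist(ds$family_ids)))
})

test_that("simulated families carry the DEFL cysteine scaffold", {
  for (s in c(7, 42)) {
    ds <- simulate_family(crp810_preset(), seed = s)
    expect_equal(length(ds$truth$cys_codons), 6L)
    # the last two scaffold cysteines form the C-terminal CXC motif
    tailc <- tail(ds$truth$cys_codons, 2)
    expect_equal(diff(tailc), 2)
    intact <- setdiff(unlist(ds$family_ids), names(ds$truth$pseudogenes))
    counts <- integer(0)
    kept <- integer(0)
    cxc <- logical(0)
    for (id in intact) {
      p <- suppressWarnings(deflevol:::.translate_orf(ds$cds[[id]]))
      pr <- cysteine_profile(mature_peptide(p, ds$truth$signal_codons))
      counts <- c(counts, pr$count)
      cxc <- c(cxc, pr$cxc_terminal)
      aa <- strsplit(p, "")[[1]]
      kept <- c(kept, sum(aa[ds$truth$cys_codons] == "C"))
    }
    # strong purifying selection on the scaffold: at most one cysteine
    # lost per gene, six mature cysteines the norm, CXC nearly universal
    expect_true(all(kept >= 5))
    expect_gte(mean(counts == 6), 0.6)
    expect_gte(mean(cxc), 0.85)
  }
})
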