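test_that("RBH maps identical proteomes onto themselves", {
  prot <- c(p1 = "MKTAYIAKQR", p2 = "MCDEFGHIKL", p3 = "MNPQRSTVWY")
  protB <- setNames(prot, c("q1", "q2", "q3"))
  rbh <- reciprocal_best_hits(prot, protB)
  expect_equal(rbh$id_a, c("p1", "p2", "p3"))
  expect_equal(rbh$id_b, c("q1", "q2", "q3"))

  expect_equal(nrow(reciprocal_best_hits(prot, character(0))), 0L)
})

test_that("of two near-identical paralogs only the better scorer is paired", {
  b <- c(b1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  a <- c(a1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", # exact match
         a2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVA") # one substitution
  rbh <- reciprocal_best_hits(a, b)
  expect_equal(nrow(rbh), 1L)
  expect_equal(rbh$id_a, "a1")
  expect_equal(rbh$id_b, "b1")
})

test_that("RBH output is a partial one-to-one matching", {
  set.seed(4)
  mk <- function(n, prefix) {
    setNames(vapply(seq_len(n), function(i)
      deflevol:::.translate_orf(random_cds_fixture(40)), character(1)),
      paste0(prefix, seq_len(n)))
  }
  a <- mk(6, "a")
  b <- c(mk(4, "b"), setNames(a[1:2], c("b5", "b6")))
  rbh <- suppressWarnings(reciprocal_best_hits(a, b))
  expect_false(anyDuplicated(rbh$id_a) > 0)
  expect_false(anyDuplicated(rbh$id_b) > 0)
})

fam_table <- function(starts, ends, ids = paste0("f", seq_along(starts)),
                      species = "A", scaffold = "chr1") {
  data.frame(species = species, gene_id = ids, scaffold = scaffold,
             start = starts, end = ends, strand = "+")
}

test_that("tandem arrays split at the intergenic gap threshold", {
  # gap of 11 kb keeps one array; 20 kb splits it
  t1 <- fam_table(c(1, 12000), c(1000, 13000))
  a1 <- tandem_arrays(t1, t1$gene_id, max_gap_kb = 15)
  expect_equal(length(a1), 1L)
  expect_equal(a1[[1]]$member_ids, c("f1", "f2"))

  t2 <- fam_table(c(1, 21001), c(1000, 22000))
  a2 <- tandem_arrays(t2, t2$gene_id, max_gap_kb = 15)
  expect_equal(length(a2), 2L)

  # arrays partition the family genes of each scaffold
  set.seed(8)
  starts <- cumsum(c(1, sample(2000:30000, 9)))
  t3 <- fam_table(starts, starts + 999)
  a3 <- tandem_arrays(t3, t3$gene_id, max_gap_kb = 15)
  members <- unlist(lapply(a3, `[[`, "member_ids"))
  expect_setequal(members, t3$gene_id)
  expect_equal(anyDuplicated(members), 0L)
})

test_that("tandem arrays recover the planted expansion membership", {
  ds <- simulate_family(crp810_preset(), seed = 3)
  arr <- tandem_arrays(ds$gene_table, unlist(ds$family_ids), max_gap_kb = 15)
  key <- function(x) paste(sort(x), collapse = ",")
  inferred <- vapply(arr, function(a) key(a$member_ids), character(1))
  truth <- vapply(ds$truth$arrays, function(a) key(a$member_ids),
                  character(1))
  expect_setequal(inferred, truth)
})

# two small genomes: focal family gene in A flanked by anchors that map in
# order to one scaffold of B, whose matching region holds a family gene
synteny_fixture <- function(family_in_b = TRUE, drop_anchors = FALSE) {
  ta <- data.frame(
    species = "A",
    gene_id = c("l3", "l2", "l1", "famA", "r1", "r2", "r3"),
    scaffold = "chrA", start = seq(1, by = 5000, length.out = 7),
    end = seq(1, by = 5000, length.out = 7) + 999, strand = "+")
  bid <- c("L3", "L2", "L1", if (family_in_b) "famB", "R1", "R2", "R3")
  tb <- data.frame(
    species = "B", gene_id = bid, scaffold = "chrB",
    start = seq(1, by = 5000, length.out = length(bid)),
    end = seq(1, by = 5000, length.out = length(bid)) + 999, strand = "+")
  rbh <- data.frame(id_a = c("l3", "l2", "l1", "r1", "r2", "r3"),
                    id_b = c("L3", "L2", "L1", "R1", "R2", "R3"),
                    score = 100)
  if (drop_anchors) rbh <- rbh[0, ]
  list(ta = ta, tb = tb, rbh = rbh)
}

test_that("ordered flanking anchors give a syntenic call and find the counterpart family", {
  fx <- synteny_fixture(family_in_b = TRUE)
  rep <- synteny_test("famA", fx$rbh, fx$ta, fx$tb, "famA", "famB")
  expect_true(rep$syntenic)
  expect_equal(rep$anchors_matched, 6L)
  expect_true(rep$order_preserved)
  expect_true(rep$counterpart_contains_family)

  # lineage-specific pattern: counterpart region exists but has no family
  fx2 <- synteny_fixture(family_in_b = FALSE)
  rep2 <- synteny_test("famA", fx2$rbh, fx2$ta, fx2$tb, "famA", "famB")
  expect_true(rep2$syntenic)
  expect_false(rep2$counterpart_contains_family)

  # no mapped anchors: not syntenic
  fx3 <- synteny_fixture(drop_anchors = TRUE)
  rep3 <- synteny_test("famA", fx3$rbh, fx3$ta, fx3$tb, "famA", "famB")
  expect_false(rep3$syntenic)

  # focal genes on two scaffolds is an error
  ta_bad <- fx$ta
  ta_bad$scaffold[4] <- "chrA2"
  expect_error(synteny_test(c("famA", "l1"), fx$rbh, ta_bad, fx$tb,
                            c("famA", "l1"), "famB"), "scaffold")
})

test_that("duplication history integrates tree verdict and synteny evidence", {
  syn <- function(syntenic, fam) {
    structure(list(focal_ids = "x", counterpart_scaffold = "chrB",
                   counterpart_interval = c(1, 2), anchors_used = NULL,
                   anchors_matched = 6L, order_preserved = TRUE,
                   syntenic = syntenic,
                   counterpart_contains_family = fam),
              class = "synteny_report")
  }
  # ancestral copy + expansion: one region with family, one without
  h1 <- duplication_history("species_specific",
                            list(syn(TRUE, TRUE), syn(TRUE, FALSE)))
  expect_equal(h1$verdict, "ancestral_copy_plus_lineage_specific_expansion")

  # everything mutually syntenic with family present
  h2 <- duplication_history("interleaved",
                            list(syn(TRUE, TRUE)), list(syn(TRUE, TRUE)))
  expect_equal(h2$verdict, "shared_ancestral_array")

  # no synteny information at all
  h3 <- duplication_history("species_specific", list())
  expect_equal(h3$verdict, "unresolved")
})
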