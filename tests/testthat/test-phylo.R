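make_aln <- function(rows) deflevol:::.new_alignment(names(rows), unname(rows))

test_that("distance matrices follow the p-distance and Poisson formulas", {
  aln <- make_aln(c(a = "AAAA", b = "AATT", c = "AAAA"))
  d <- distance_matrix(aln, "p_distance")
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))

  dp <- distance_matrix(aln, "poisson")
  expect_equal(dp["a", "b"], -log(1 - 0.5)) # 0.6931...

  # pairwise deletion of gap columns
  alng <- make_aln(c(a = "AA-A", b = "AATA"))
  expect_equal(distance_matrix(alng)["a", "b"], 0)

  # saturated pair under poisson is flagged
  alns <- make_aln(c(a = "AAAA", b = "TTTT"))
  expect_warning(distance_matrix(alns, "poisson"), "undefined")
})

test_that("NJ closed forms hold for two and three taxa", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(sum(t2$edge.length), 0.4)

  # three taxa: b1 = (d12 + d13 - d23) / 2 etc.
  d3 <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.6,
                 0.5, 0.6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["a"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(bl[["b"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(bl[["c"]], (0.5 + 0.6 - 0.3) / 2)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("NJ recovers additive trees exactly", {
  set.seed(31)
  for (rep in 1:5) {
    true <- ape::rtree(6)
    dm <- cophenetic(true)
    est <- nj_tree(dm[order(rownames(dm)), order(colnames(dm))])
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    resid <- max(abs(cophenetic(est)[rownames(dm), colnames(dm)] - dm))
    expect_lt(resid, 1e-9)
  }
})

test_that("bipartitions are the nontrivial splits", {
  quartet <- ape::read.tree(text = "((A,B),(C,D));")
  bp <- bipartitions(quartet)
  expect_equal(length(bp), 1L)
  expect_setequal(bp[[1]]$a, c("C", "D"))
  expect_setequal(bp[[1]]$b, c("A", "B"))

  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_equal(length(bipartitions(star)), 0L)

  # binary unrooted n-leaf tree has n - 3 nontrivial splits
  set.seed(2)
  t8 <- ape::unroot(ape::rtree(8))
  expect_equal(length(bipartitions(t8)), 8 - 3)

  # relabeling permutes but does not change the split structure
  t8b <- t8
  perm <- setNames(sample(t8$tip.label), t8$tip.label)
  t8b$tip.label <- unname(perm[t8$tip.label])
  keyset <- function(tr) {
    sort(vapply(bipartitions(tr), function(s)
      paste(sort(c(paste(sort(s$a), collapse = ","),
                   paste(sort(s$b), collapse = ","))), collapse = "|"),
      character(1)))
  }
  mapped <- sort(vapply(bipartitions(t8), function(s)
    paste(sort(c(paste(sort(unname(perm[s$a])), collapse = ","),
                 paste(sort(unname(perm[s$b])), collapse = ","))),
          collapse = "|"), character(1)))
  expect_equal(keyset(t8b), mapped)
})

# four clean clades, strongly divergent, for bootstrap checks
clade_alignment <- function(n_per = 3, len_codons = 120, seed = 77) {
  set.seed(seed)
  root <- random_cds_fixture(len_codons)
  seqs <- character(0)
  for (cl in 1:4) {
    anc <- deflevol:::.evolve_cds(root, 0.4, 1)
    for (i in seq_len(n_per)) {
      seqs[sprintf("c%d_%d", cl, i)] <- deflevol:::.evolve_cds(anc, 0.03, 1)
    }
  }
  progressive_msa(seqs, scoring_params("NUC"))
}

test_that("bootstrap support is deterministic per seed, bounded, and finds clean clades", {
  msa <- clade_alignment()
  t1 <- bootstrap_support(msa, replicates = 200, seed = 5)
  t2 <- bootstrap_support(msa, replicates = 200, seed = 5)
  expect_equal(attr(t1, "splits"), attr(t2, "splits"))

  sp <- attr(t1, "splits")
  expect_true(all(sp$support >= 0 & sp$support <= 100))

  key <- deflevol:::.split_key(sprintf("c1_%d", 1:3), t1$tip.label)
  expect_gte(sp$support[match(key, sp$key)], 95)
})

test_that("bootstrap supports converge between seeds at 1000 replicates", {
  msa <- clade_alignment(n_per = 2, len_codons = 100)
  s1 <- attr(bootstrap_support(msa, replicates = 1000, seed = 1), "splits")
  s2 <- attr(bootstrap_support(msa, replicates = 1000, seed = 2), "splits")
  m <- merge(s1, s2, by = "key")
  strong <- m[m$support.x >= 90 | m$support.y >= 90, ]
  expect_true(nrow(strong) >= 1)
  expect_true(all(abs(strong$support.x - strong$support.y) <= 5))
})

test_that("newick I/O round-trips topology, lengths and support labels", {
  msa <- clade_alignment(n_per = 2, len_codons = 60, seed = 3)
  tr <- bootstrap_support(msa, replicates = 50, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tmp)
  back <- read_newick(tmp)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(sort(back$node.label), sort(tr$node.label))
})
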