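test_that("NG86 site counts match single-change enumeration", {
  expect_equal(unname(ng86_site_counts("TTT")["S"]), 1 / 3)
  expect_equal(unname(ng86_site_counts("ATG")["S"]), 0)
  expect_equal(unname(ng86_site_counts("ATG")["N"]), 3)

  # S + N = 3L for random stop-free sequences
  set.seed(13)
  for (rep in 1:5) {
    cds <- random_cds_fixture(sample(5:40, 1))
    sn <- ng86_site_counts(cds)
    expect_equal(unname(sn["S"] + sn["N"]), nchar(cds), tolerance = 1e-9)
  }
  expect_error(ng86_site_counts("TTTTAA"), "stop")
  expect_error(ng86_site_counts("TT"), "divisible")
  expect_error(ng86_site_counts("TT-TTT"), "gaps")
})

test_that("pairwise NG86 classifies single and multi-hit codons by pathways", {
  # identical sequences: no differences, omega undefined with dS_zero
  st0 <- ng86_pairwise("TTTAAA", "TTTAAA")
  expect_equal(st0$Sd + st0$Nd, 0)
  expect_true(st0$flags$dS_zero)
  expect_true(is.na(st0$omega))

  # single synonymous change
  st1 <- ng86_pairwise("TTT", "TTC")
  expect_equal(st1$Sd, 1)
  expect_equal(st1$Nd, 0)

  # two pathways, one blocked contribution-free: TTT <-> GTA
  st2 <- ng86_pairwise("TTT", "GTA")
  expect_equal(st2$Sd, 0.5)
  expect_equal(st2$Nd, 1.5)

  expect_error(ng86_pairwise("TTT", "TTTAAA"), "length")
})

test_that("pairwise NG86 is symmetric and agrees with the pathway oracle", {
  set.seed(23)
  for (rep in 1:4) {
    a <- random_cds_fixture(30)
    b <- deflevol:::.evolve_cds(a, 0.25, 1)
    ab <- ng86_pairwise(a, b)
    ba <- ng86_pairwise(b, a)
    for (f in c("S", "N", "Sd", "Nd", "dS", "dN"))
      expect_equal(ab[[f]], ba[[f]], tolerance = 1e-12)

    # per-codon differences against the independent enumeration oracle
    ca <- deflevol:::.split_codons(a)
    cb <- deflevol:::.split_codons(b)
    keep <- !(ca %in% c("TAA", "TAG", "TGA")) &
      !(cb %in% c("TAA", "TAG", "TGA"))
    oracle <- rowSums(vapply(which(keep), function(i)
      ng86_pair_oracle(ca[i], cb[i]), numeric(2)))
    expect_equal(ab$Sd, unname(oracle["sd"]), tolerance = 1e-9)
    expect_equal(ab$Nd, unname(oracle["nd"]), tolerance = 1e-9)
  }
})

test_that("the Jukes-Cantor domain and zero-dS cases are flagged, not infinite", {
  # TTT vs CTA: Sd = 1 against mean S = 5/6, so pS = 1.2 exceeds the
  # Jukes-Cantor domain and dS (hence omega) must be NA, never infinite
  st <- ng86_pairwise("TTT", "CTA")
  expect_equal(st$Sd, 1)
  expect_gt(st$pS, 0.75)
  expect_true(st$flags$jc_domain_error)
  expect_true(is.na(st$dS))
  expect_true(is.na(st$omega))
})

test_that("Fisher exact matches full enumeration for margins <= 12", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1.0)
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), 0.1) # (1 + 1) / C(6,3)
  expect_equal(fisher_exact_2x2(0, 5, 7, 0),
               fisher_oracle_2x2(0, 5, 7, 0), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)

  set.seed(3)
  for (rep in 1:25) {
    x <- sample(0:12, 4, replace = TRUE)
    expect_equal(fisher_exact_2x2(x[1], x[2], x[3], x[4]),
                 fisher_oracle_2x2(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-9)
  }
})

test_that("the exact binomial test matches enumeration and the printed assay call", {
  expect_equal(binomial_test_two_sided(6, 12), 1.0)
  expect_equal(binomial_test_two_sided(0, 11), 2 / 2048)
  # 1 of 12 pollen tubes attracted: p = 26/4096 < 0.01
  p <- binomial_test_two_sided(1, 12)
  expect_equal(p, 26 / 4096, tolerance = 1e-9)
  expect_lt(p, 0.01)

  set.seed(17)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    k <- sample(0:n, 1)
    expect_equal(binomial_test_two_sided(k, n),
                 binom_oracle_two_sided(k, n), tolerance = 1e-9)
  }
  expect_error(binomial_test_two_sided(0, 0), "positive")
})

test_that("MK test counts polymorphic and fixed changes in codon context", {
  # uninformative panel: no variation anywhere
  same <- paste(rep("ATGAAAGGG", 2), collapse = "")
  mk0 <- mk_test(c(i1 = same, i2 = same), same)
  expect_equal(mk0$Pn + mk0$Ps + mk0$Dn + mk0$Ds, 0L)
  expect_equal(mk0$p_two_sided, 1)

  # constructed alignment with exactly Pn=2, Ps=10, Dn=10, Ds=2
  syn_poly <- c("GGA", "GGG", "GGA")   # ingroup segregates synonymously
  non_poly <- c("AAA", "AAC", "AAA")   # ingroup segregates nonsynonymously
  syn_fix <- c("GGA", "GGA", "GGG")    # fixed synonymous difference
  non_fix <- c("AAA", "AAA", "AAC")    # fixed nonsynonymous difference
  cols <- c(rep(list(non_poly), 2), rep(list(syn_poly), 10),
            rep(list(non_fix), 10), rep(list(syn_fix), 2))
  seqs <- apply(do.call(rbind, cols), 2, paste, collapse = "")
  mk <- mk_test(c(i1 = seqs[1], i2 = seqs[2]), seqs[3])
  expect_equal(c(mk$Pn, mk$Ps, mk$Dn, mk$Ds), c(2L, 10L, 10L, 2L))
  expect_equal(mk$p_two_sided, fisher_exact_2x2(2, 10, 10, 2))
  expect_equal(mk$neutrality_index, (2 / 10) / (10 / 2))

  expect_error(mk_test(c(i1 = same), same), "2 ingroup")
})

test_that("MK test detects elevated nonsynonymous fixation", {
  # omega jumps to 3 on the divergence branch only; polymorphism neutral.
  # Replicates with fewer than 30 fixed differences are uninformative for
  # this property and are not scored.
  rej <- 0L
  n_used <- 0L
  for (s in 1:40) {
    pan <- simulate_mk_panel(n_ingroup = 8, n_codons = 400, t_div = 0.06,
                             t_poly = 0.015, omega_div = 3, omega_poly = 1,
                             seed = 400 + s)
    mk <- mk_test(pan$ingroup, pan$outgroup)
    if (mk$Dn + mk$Ds < 30) next
    n_used <- n_used + 1L
    if (mk$p_two_sided < 0.05) rej <- rej + 1L
  }
  expect_gte(n_used, 30L)
  expect_gt(rej / n_used, 0.5)
})
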