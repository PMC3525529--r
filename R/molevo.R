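# Nei-Gojobori (1986) dN/dS with pathway averaging and Jukes-Cantor
# correction, the McDonald-Kreitman test, and the exact 2x2 / binomial
# tests used alongside them.

#' NG86 synonymous and nonsynonymous site counts
#'
#' For every codon position, the synonymous site fraction is the number of
#' the 3 possible single-nucleotide changes that preserve the amino acid,
#' divided by 3; changes creating stop codons count as nonsynonymous.
#' `S + N = 3 * (number of codons)` always.
#'
#' @param cds Ungapped CDS (length divisible by 3, no in-frame stop
#'   codons, alphabet ACGT).
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @examples
#' ng86_site_counts("TTT") # S = 1/3
#' @export
ng86_site_counts <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) == 0L || nchar(cds) %% 3L != 0L)
    stop("CDS must be non-empty with length divisible by 3")
  if (grepl("[^ACGT]", cds))
    stop("CDS must contain only A, C, G, T (no gaps or ambiguities)")
  codons <- .split_codons(cds)
  if (any(.is_stop(codons)))
    stop("in-frame stop codon at codon ",
         which(.is_stop(codons))[1])
  s <- sum(.ng86_sites()[codons])
  c(S = s, N = 3 * length(codons) - s)
}

#' Pairwise NG86 dN/dS
#'
#' Counts synonymous/nonsynonymous sites (averaged over the two sequences)
#' and differences between two codon-aligned CDSs. Codon pairs differing
#' at 2 or 3 positions are averaged over all 2 or 6 mutational pathways;
#' pathways passing through stop codons are excluded (if every pathway is
#' blocked, all are used and a flag is set). Proportions are corrected
#' with the Jukes-Cantor formula `d = -(3/4) ln(1 - (4/3) p)`.
#'
#' Codon columns containing a gap in either sequence are deleted pairwise;
#' columns with a stop codon or an ambiguous base in either sequence are
#' also dropped (counted in `n_dropped`).
#'
#' @param a,b Codon-aligned nucleotide strings of equal length.
#' @return A `codon_pair_stats` object: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `dS`, `dN`, `omega`, `n_codons`, `n_dropped` and logical `flags`
#'   (`dS_zero`, `jc_domain_error`, `stop_blocked_pathways`). `omega` is
#'   `NA` (never infinite) when `dS` is zero or undefined.
#' @export
ng86_pairwise <- function(a, b) {
  a <- toupper(a)
  b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("aligned length not divisible by 3")
  ca <- .split_codons(a)
  cb <- .split_codons(b)
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  keep <- clean & !.is_stop(ca) & !.is_stop(cb)
  n_dropped <- sum(!keep)
  ca <- ca[keep]
  cb <- cb[keep]
  if (!length(ca)) stop("no comparable codon columns left")

  sites <- .ng86_sites()
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  pt <- .ng86_pair_tables()
  idx <- cbind(match(ca, rownames(pt$sd)), match(cb, colnames(pt$sd)))
  Sd <- sum(pt$sd[idx])
  Nd <- sum(pt$nd[idx])
  blocked <- any(pt$blocked[idx])

  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  jc_err <- pS >= 0.75 || pN >= 0.75
  ds_zero <- !is.na(dS) && dS == 0
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS

  structure(
    list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         dS = dS, dN = dN, omega = omega,
         n_codons = length(ca), n_dropped = n_dropped,
         flags = list(dS_zero = ds_zero, jc_domain_error = jc_err,
                      stop_blocked_pathways = blocked)),
    class = "codon_pair_stats"
  )
}

#' @export
print.codon_pair_stats <- function(x, ...) {
  cat(sprintf(
    "<codon_pair_stats> %d codons: dN=%.4f dS=%.4f omega=%s (Sd=%.2f Nd=%.2f)\n",
    x$n_codons, x$dN, x$dS,
    if (is.na(x$omega)) "NA" else sprintf("%.3f", x$omega), x$Sd, x$Nd))
  invisible(x)
}

#' All-pairs NG86 dN/dS for a codon alignment
#'
#' @param codon_msa A codon-level `alignment` (e.g. from
#'   [codon_backtranslate()]).
#' @return List of matrices `dN`, `dS`, `omega` (taxa x taxa; `NA` on the
#'   diagonal and where undefined) and `pairs`, a data frame with one row
#'   per pair including the `dS_zero` flag.
#' @export
dnds_matrix <- function(codon_msa) {
  ids <- codon_msa$ids
  n <- length(ids)
  if (n < 2L) stop("need at least two sequences")
  dN <- dS <- om <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  rows <- list()
  for (ij in combn(n, 2, simplify = FALSE)) {
    st <- ng86_pairwise(codon_msa$rows[[ids[ij[1]]]],
                        codon_msa$rows[[ids[ij[2]]]])
    dN[ij[1], ij[2]] <- dN[ij[2], ij[1]] <- st$dN
    dS[ij[1], ij[2]] <- dS[ij[2], ij[1]] <- st$dS
    om[ij[1], ij[2]] <- om[ij[2], ij[1]] <- st$omega
    rows[[length(rows) + 1L]] <- data.frame(
      id1 = ids[ij[1]], id2 = ids[ij[2]], dN = st$dN, dS = st$dS,
      omega = st$omega, dS_zero = st$flags$dS_zero)
  }
  list(dN = dN, dS = dS, omega = om, pairs = do.call(rbind, rows))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p sums the hypergeometric probabilities of all tables
#' with the observed margins whose point probability does not exceed the
#' observed one. A table with any zero margin is degenerate and returns
#' p = 1.
#'
#' @param a,b,c,d Nonnegative integer cell counts, row-wise
#'   (`[[a, b], [c, d]]`).
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x))) stop("counts must be nonnegative integers")
  m <- matrix(as.integer(round(x)), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) return(1)
  stats::fisher.test(m)$p.value
}

#' Exact two-sided binomial test
#'
#' Two-sided p summing `P(X = i)` over all outcomes no more probable than
#' the observed one, with `X ~ Binomial(n, p0)`.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials (`> 0`).
#' @param p0 Null success probability (default 0.5, a 1:1 ratio).
#' @return The two-sided p-value.
#' @export
binomial_test_two_sided <- function(k, n, p0 = 0.5) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  stats::binom.test(k, n, p = p0)$p.value
}

#' McDonald-Kreitman test
#'
#' Contrasts within-species polymorphism against between-species fixed
#' differences, each partitioned into synonymous and nonsynonymous
#' changes, via a Fisher exact test on `[[Pn, Ps], [Dn, Ds]]`.
#'
#' A nucleotide site is polymorphic if the ingroup panel segregates at
#' least two states there (each segregating state beyond the first counts
#' one change) and fixed if the ingroup is invariant but differs from the
#' outgroup. Changes are classified by their effect in the context of the
#' majority ingroup codon; codons carrying several fixed differences are
#' resolved by NG86-style pathway averaging, and the fractional fixed
#' counts are accumulated across sites before a single final rounding.
#' Codon columns with gaps, ambiguities or stop codons in any sequence
#' are excluded.
#'
#' @param ingroup Named character vector of >= 2 aligned within-species
#'   CDSs.
#' @param outgroup A single aligned outgroup CDS of the same length.
#' @return An `mk_result`: integer `Dn`, `Ds`, `Pn`, `Ps` (plus raw
#'   fractional `Dn_raw`, `Ds_raw`), `p_two_sided`, `neutrality_index`
#'   (`(Pn/Ps)/(Dn/Ds)`, `NA` when undefined) and `n_codons_used`.
#' @export
mk_test <- function(ingroup, outgroup) {
  ingroup <- unlist(as.list(ingroup))
  if (length(ingroup) < 2L) stop("need at least 2 ingroup sequences")
  if (length(outgroup) != 1L) stop("outgroup must be a single sequence")
  seqs <- toupper(c(ingroup, .out = unname(outgroup)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences differ in aligned length")
  if (L %% 3L != 0L) stop("aligned length not divisible by 3")

  n_in <- length(ingroup)
  cod <- vapply(seqs, .split_codons, character(L / 3))
  if (L / 3 == 1L) cod <- matrix(cod, nrow = 1L, dimnames = NULL)
  # drop columns with gaps/ambiguities/stops in any sequence
  bad <- apply(cod, 1, function(cc) any(grepl("[^ACGT]", cc)) ||
                 any(.is_stop(cc)))
  cod <- cod[!bad, , drop = FALSE]
  if (nrow(cod) == 0L) stop("no usable codon columns")

  Pn <- Ps <- 0L
  Dn_raw <- Ds_raw <- 0
  for (r in seq_len(nrow(cod))) {
    cin <- cod[r, seq_len(n_in)]
    cout <- cod[r, n_in + 1L]
    bg <- names(sort(table(cin), decreasing = TRUE))[1] # majority codon
    bin <- do.call(rbind, strsplit(cin, ""))
    bout <- strsplit(cout, "")[[1]]
    bbg <- strsplit(bg, "")[[1]]
    fixed_pos <- integer(0)
    for (p in 1:3) {
      states <- unique(bin[, p])
      if (length(states) >= 2L) {
        # polymorphic: one change per segregating state beyond the majority
        for (s in setdiff(states, bbg[p])) {
          mut <- bg
          substr(mut, p, p) <- s
          syn <- !.is_stop(mut) && .codon_aa(mut) == .codon_aa(bg)
          if (syn) Ps <- Ps + 1L else Pn <- Pn + 1L
        }
      } else if (states != bout[p]) {
        fixed_pos <- c(fixed_pos, p)
      }
    }
    if (length(fixed_pos)) {
      target <- bg
      for (p in fixed_pos) substr(target, p, p) <- bout[p]
      if (.is_stop(target) || .is_stop(bg)) {
        Dn_raw <- Dn_raw + length(fixed_pos) # stop-involving: nonsynonymous
      } else {
        v <- .ng86_pair_one(bg, target)
        Dn_raw <- Dn_raw + v[["nd"]]
        Ds_raw <- Ds_raw + v[["sd"]]
      }
    }
  }
  Dn <- as.integer(floor(Dn_raw + 0.5))
  Ds <- as.integer(floor(Ds_raw + 0.5))
  p <- fisher_exact_2x2(Pn, Ps, Dn, Ds)
  ni <- if (Ps > 0L && Ds > 0L && Dn > 0L)
    (Pn / Ps) / (Dn / Ds) else NA_real_

  structure(
    list(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps,
         Dn_raw = Dn_raw, Ds_raw = Ds_raw,
         p_two_sided = p, neutrality_index = ni,
         n_codons_used = nrow(cod)),
    class = "mk_result"
  )
}

#' @export
print.mk_result <- function(x, ...) {
  cat(sprintf(
    "<mk_result> Pn=%d Ps=%d | Dn=%d Ds=%d  Fisher p=%.4g  NI=%s\n",
    x$Pn, x$Ps, x$Dn, x$Ds, x$p_two_sided,
    if (is.na(x$neutrality_index)) "NA"
    else sprintf("%.3f", x$neutrality_index)))
  invisible(x)
}
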