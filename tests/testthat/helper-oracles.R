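# Independent brute-force oracles used to validate the fast
# implementations on small inputs.

# exhaustive enumeration of all global alignments with affine gaps
# (gap run of length L costs open + (L-1) * ext); returns the optimum score
brute_force_align_score <- function(a, b, params) {
  sm <- params$submat
  go <- params$gap_open
  ge <- params$gap_extend
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1L, j + 1L, score + sm[A[i], B[j]], "M")
    if (i <= length(A))
      rec(i + 1L, j, score - if (last == "X") ge else go, "X")
    if (j <= length(B))
      rec(i, j + 1L, score - if (last == "Y") ge else go, "Y")
  }
  rec(1L, 1L, 0, "M")
  best
}

# full hypergeometric enumeration of the two-sided Fisher p for a 2x2 table
fisher_oracle_2x2 <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - r2)
  hi <- min(k, r1)
  probs <- stats::dhyper(lo:hi, r1, r2, k)
  pobs <- stats::dhyper(a, r1, r2, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# exact two-sided binomial p by direct enumeration
binom_oracle_two_sided <- function(k, n, p0 = 0.5) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# pathway-averaged NG86 difference counts for one codon pair, written as a
# plain recursive enumeration over substitution orderings
ng86_pair_oracle <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(diffs)) return(c(sd = 0, nd = 0))
  perm <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm(v[-i]), function(p) c(v[i], p))))
  }
  paths <- lapply(perm(diffs), function(o) {
    cur <- a
    sd <- nd <- 0
    ok <- TRUE
    for (p in o) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (nxt %in% stops && nxt != b) ok <- FALSE
      syn <- !(cur %in% stops) && !(nxt %in% stops) &&
        gc[[cur]] == gc[[nxt]]
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, ok = ok)
  })
  usable <- Filter(function(p) p$ok, paths)
  if (!length(usable)) usable <- paths
  c(sd = mean(vapply(usable, `[[`, 0, "sd")),
    nd = mean(vapply(usable, `[[`, 0, "nd")))
}

# random stop-free CDS for property tests
random_cds_fixture <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  pool <- names(gc)[gc != "*"]
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}
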