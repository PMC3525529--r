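# Genetic-code helpers shared by the sequence, molecular-evolution and
# simulation modules. Standard nuclear code only; stop set {TAA, TAG, TGA}.

.BASES <- c("A", "C", "G", "T")

.genetic_code <- function() {
  if (is.null(.deflevol_cache$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .deflevol_cache$gc <- setNames(as.character(gc), names(gc))
  }
  .deflevol_cache$gc
}

.codon_aa <- function(codons) {
  gc <- .genetic_code()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X" # any codon containing N or another ambiguity
  aa
}

.split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

.is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

#' Translate a coding sequence
#'
#' Translates a nucleotide CDS with the standard genetic code, one residue
#' per codon. Internal stop codons are rendered as `*` and reported; codons
#' containing `N` (or any non-ACGT character) translate to `X`. An
#' incomplete trailing codon is trimmed with a warning.
#'
#' @param cds A single nucleotide string (alphabet `A`, `C`, `G`, `T`, `N`).
#' @param trim_incomplete Trim a trailing 1-2 nt partial codon (default) or
#'   error on it.
#' @return A list with `protein` (one character per codon, `*` for stops),
#'   `premature_stop` (`TRUE` if a stop occurs before the final codon),
#'   `premature_stop_codon` (1-based codon index of the first such stop, or
#'   `NA`), and `terminal_stop` (`TRUE` if the final codon is a stop).
#' @examples
#' translate_cds("ATGTTT")$protein # "MF"
#' translate_cds("ATGTAATTT") # internal stop at codon 2
#' @export
translate_cds <- function(cds, trim_incomplete = TRUE) {
  if (!is.character(cds) || length(cds) != 1L || is.na(cds) || nchar(cds) == 0L)
    stop("'cds' must be a single non-empty nucleotide string")
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds))
    stop("'cds' contains characters outside {A,C,G,T,N}")
  rem <- nchar(cds) %% 3L
  if (rem != 0L) {
    if (!trim_incomplete)
      stop("CDS length not divisible by 3")
    warning("trimming incomplete trailing codon (", rem, " nt)")
    cds <- substr(cds, 1L, nchar(cds) - rem)
    if (nchar(cds) == 0L) stop("CDS shorter than one codon")
  }
  codons <- .split_codons(cds)
  aa <- .codon_aa(codons)
  prot <- paste(aa, collapse = "")
  stops <- which(aa == "*")
  internal <- stops[stops < length(aa)]
  list(
    protein = prot,
    premature_stop = length(internal) > 0L,
    premature_stop_codon = if (length(internal)) internal[1L] else NA_integer_,
    terminal_stop = length(stops) > 0L && stops[length(stops)] == length(aa)
  )
}

# Protein sequence up to (excluding) the first stop, for record plumbing.
.translate_orf <- function(cds) {
  tr <- translate_cds(cds)
  sub("\\*.*$", "", tr$protein)
}

# ---- NG86 site and pathway tables ------------------------------------------

# Per-codon synonymous site count: at each position the fraction (of the 3
# single-nucleotide changes) that preserve the amino acid; changes into stop
# codons count as nonsynonymous. Stop codons themselves are NA.
.ng86_sites <- function() {
  if (!is.null(.deflevol_cache$ng86_sites)) return(.deflevol_cache$ng86_sites)
  codons <- names(.genetic_code())
  s <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (.is_stop(cd)) { s[cd] <- NA_real_; next }
    aa0 <- .codon_aa(cd)
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(.BASES, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- b
        if (!.is_stop(mut) && .codon_aa(mut) == aa0) syn <- syn + 1
      }
    }
    s[cd] <- syn / 3
  }
  .deflevol_cache$ng86_sites <- s
  s
}

.perms <- list(
  `1` = matrix(1L, 1, 1),
  `2` = rbind(c(1L, 2L), c(2L, 1L)),
  `3` = rbind(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
)

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair (both non-stop). Pathways passing through an intermediate stop codon
# are excluded; if every pathway is blocked, all are used and `blocked` set.
.ng86_pair_one <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0, blocked = 0))
  perms <- .perms[[as.character(d)]]
  tot_sd <- tot_nd <- 0
  n_ok <- 0L
  all_sd <- all_nd <- 0
  for (r in seq_len(nrow(perms))) {
    cur <- a
    sd <- nd <- 0
    ok <- TRUE
    for (p in pos[perms[r, ]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (.is_stop(nxt) && nxt != b) ok <- FALSE
      if (!.is_stop(cur) && !.is_stop(nxt) &&
          .codon_aa(cur) == .codon_aa(nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    all_sd <- all_sd + sd
    all_nd <- all_nd + nd
    if (ok) {
      tot_sd <- tot_sd + sd
      tot_nd <- tot_nd + nd
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok > 0L) {
    c(sd = tot_sd / n_ok, nd = tot_nd / n_ok, blocked = 0)
  } else {
    c(sd = all_sd / nrow(perms), nd = all_nd / nrow(perms), blocked = 1)
  }
}

.ng86_pair_tables <- function() {
  if (!is.null(.deflevol_cache$ng86_pairs)) return(.deflevol_cache$ng86_pairs)
  codons <- names(.genetic_code())
  n <- length(codons)
  sd <- nd <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  blocked <- matrix(FALSE, n, n, dimnames = list(codons, codons))
  ok <- !.is_stop(codons)
  for (i in which(ok)) {
    for (j in which(ok)) {
      if (j < i) next
      v <- .ng86_pair_one(codons[i], codons[j])
      sd[i, j] <- sd[j, i] <- v[["sd"]]
      nd[i, j] <- nd[j, i] <- v[["nd"]]
      blocked[i, j] <- blocked[j, i] <- v[["blocked"]] > 0
    }
  }
  .deflevol_cache$ng86_pairs <- list(sd = sd, nd = nd, blocked = blocked)
  .deflevol_cache$ng86_pairs
}
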