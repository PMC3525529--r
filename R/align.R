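# Global pairwise alignment, percent identity, progressive multiple
# alignment and codon back-translation. The affine-gap profile aligner
# itself is compiled (src/align.cpp); a gap run of length L costs
# gap_open + (L - 1) * gap_extend.

#' Alignment scoring parameters
#'
#' @param matrix `"BLOSUM62"` (protein; the Biostrings copy) or `"NUC"`
#'   (nucleotide: match +2, mismatch -1, `N` scores 0 against everything).
#' @param gap_open,gap_extend Nonnegative gap penalties; a gap run of
#'   length L costs `gap_open + (L - 1) * gap_extend`.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(matrix = c("BLOSUM62", "NUC"),
                           gap_open = 10, gap_extend = 0.5) {
  matrix <- match.arg(matrix)
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  structure(list(matrix = matrix, submat = .get_submat(matrix),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_params")
}

.get_submat <- function(name) {
  key <- paste0("submat_", name)
  if (!is.null(.deflevol_cache[[key]])) return(.deflevol_cache[[key]])
  m <- switch(name,
    BLOSUM62 = {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$BLOSUM62
    },
    NUC = {
      b <- c("A", "C", "G", "T", "N")
      m <- matrix(-1, 5, 5, dimnames = list(b, b))
      diag(m) <- 2
      m["N", ] <- 0
      m[, "N"] <- 0
      m
    },
    stop("unknown substitution matrix: ", name)
  )
  .deflevol_cache[[key]] <- m
  m
}

# substitution matrix padded with a zero-scoring gap symbol
.padded_submat <- function(params) {
  m <- params$submat
  out <- rbind(cbind(m, `-` = 0), `-` = 0)
  rownames(out)[nrow(out)] <- "-"
  out
}

.rows_to_profile <- function(rows, symbols) {
  chars <- strsplit(unname(rows), "")
  len <- length(chars[[1]])
  mat <- matrix(0, nrow = length(symbols), ncol = len,
                dimnames = list(symbols, NULL))
  for (r in chars) {
    bad <- setdiff(unique(r), symbols)
    if (length(bad))
      stop("symbol(s) not in substitution alphabet: ",
           paste(bad, collapse = ", "))
    idx <- match(r, symbols)
    mat[cbind(idx, seq_len(len))] <- mat[cbind(idx, seq_len(len))] + 1
  }
  mat / length(chars)
}

.new_alignment <- function(ids, rows, score = NA_real_, params = NULL) {
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) stop("alignment rows differ in length")
  structure(list(ids = ids, rows = setNames(rows, ids),
                 score = score, params = params),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d sequence(s), %d column(s)",
              length(x$rows), nchar(x$rows[[1]])))
  if (!is.na(x$score)) cat(sprintf(", score %.2f", x$score))
  cat("\n")
  invisible(x)
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment of two sequences under the given scoring
#' parameters, with a fixed traceback tie-break (match/mismatch preferred
#' over a gap in the second sequence, preferred over a gap in the first) so
#' results are reproducible.
#'
#' @param a Either a single sequence, or a named character vector of two
#'   sequences (in which case `b` may be omitted or hold the parameters).
#' @param b Second sequence, or a `scoring_params` object.
#' @param params Scoring parameters; see [scoring_params()].
#' @return An `alignment` object with `ids`, gapped `rows`, `score`.
#' @examples
#' global_align("ACDE", "ACE", scoring_params("BLOSUM62"))
#' @export
global_align <- function(a, b = NULL, params = scoring_params()) {
  if (inherits(b, "scoring_params")) {
    params <- b
    b <- NULL
  }
  if (is.null(b)) {
    if (length(a) != 2L) stop("need exactly two sequences")
    ids <- names(a) %||% c("seq1", "seq2")
    b <- a[[2]]
    a <- a[[1]]
  } else {
    ids <- c(names(a) %||% "seq1", names(b) %||% "seq2")
    a <- unname(a)
    b <- unname(b)
  }
  if (nchar(a) == 0L && nchar(b) == 0L) stop("both sequences are empty")
  a <- toupper(a)
  b <- toupper(b)
  sub <- .padded_submat(params)
  sym <- rownames(sub)
  pa <- .rows_to_profile(a, sym)
  pb <- .rows_to_profile(b, sym)
  res <- align_profiles_cpp(pa, pb, sub, params$gap_open, params$gap_extend)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  row_a <- ifelse(res$path_a > 0L, ca[pmax(res$path_a, 1L)], "-")
  row_b <- ifelse(res$path_b > 0L, cb[pmax(res$path_b, 1L)], "-")
  .new_alignment(ids, c(paste(row_a, collapse = ""),
                        paste(row_b, collapse = "")),
                 score = res$score, params = params)
}

#' Percent identity between two aligned rows
#'
#' @param alignment An `alignment` object.
#' @param pair Ids of the two rows to compare (default: first two).
#' @param denominator `"aligned_span"` (columns where at least one of the
#'   two rows is non-gap; the default) or `"shorter"` (length of the
#'   shorter degapped sequence).
#' @return Percent identity in \[0, 100\]; symmetric in the pair.
#' @export
percent_identity <- function(alignment, pair = alignment$ids[1:2],
                             denominator = c("aligned_span", "shorter")) {
  denominator <- match.arg(denominator)
  if (!all(pair %in% alignment$ids)) stop("pair ids not found in alignment")
  x <- strsplit(alignment$rows[[pair[1]]], "")[[1]]
  y <- strsplit(alignment$rows[[pair[2]]], "")[[1]]
  covered <- x != "-" | y != "-"
  match_n <- sum(x == y & x != "-")
  denom <- if (denominator == "aligned_span") sum(covered)
           else min(sum(x != "-"), sum(y != "-"))
  if (denom == 0L) stop("rows have no aligned coverage")
  100 * match_n / denom
}

#' Progressive multiple sequence alignment
#'
#' Aligns sequences progressively: all pairwise global alignments give a
#' percent-identity distance matrix, a UPGMA guide tree orders the merges,
#' and clusters are merged by affine-gap profile-profile alignment. Inputs
#' are recoverable by removing gaps from their rows, and no column is
#' all-gap.
#'
#' @param seqs Named character vector of sequences (unique ids).
#' @param params Scoring parameters; see [scoring_params()].
#' @return An `alignment` object.
#' @export
progressive_msa <- function(seqs, params = scoring_params()) {
  seqs <- unlist(as.list(seqs))
  n <- length(seqs)
  if (n < 1L) stop("need at least one sequence")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in input")
  seqs <- toupper(seqs)
  if (n == 1L) return(.new_alignment(names(seqs), unname(seqs), 0, params))
  if (n == 2L) return(global_align(seqs, params))

  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (ij in combn(n, 2, simplify = FALSE)) {
    aln <- global_align(seqs[ij], params)
    d[ij[1], ij[2]] <- d[ij[2], ij[1]] <- 1 - percent_identity(aln) / 100
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")

  sub <- .padded_submat(params)
  sym <- rownames(sub)
  clusters <- vector("list", nrow(hc$merge))
  get_cluster <- function(k) {
    if (k < 0) list(ids = names(seqs)[-k], rows = unname(seqs[-k]))
    else clusters[[k]]
  }
  for (m in seq_len(nrow(hc$merge))) {
    ca <- get_cluster(hc$merge[m, 1])
    cb <- get_cluster(hc$merge[m, 2])
    res <- align_profiles_cpp(.rows_to_profile(ca$rows, sym),
                              .rows_to_profile(cb$rows, sym),
                              sub, params$gap_open, params$gap_extend)
    clusters[[m]] <- list(
      ids = c(ca$ids, cb$ids),
      rows = c(.expand_rows(ca$rows, res$path_a),
               .expand_rows(cb$rows, res$path_b))
    )
  }
  final <- clusters[[nrow(hc$merge)]]
  ord <- match(names(seqs), final$ids)
  .new_alignment(final$ids[ord], final$rows[ord], params = params)
}

.expand_rows <- function(rows, path) {
  vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    out <- rep("-", length(path))
    out[path > 0L] <- ch[path[path > 0L]]
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Back-translate a protein alignment to codons
#'
#' Converts each amino-acid column into the corresponding 3-nt codon block
#' of the source CDS (gaps become `---`), producing the codon-level
#' alignment needed for dN/dS. A trailing stop codon on a CDS is dropped.
#'
#' @param protein_msa An `alignment` of proteins.
#' @param cds_by_id Named character vector of CDSs covering every row id.
#' @return A codon-level `alignment` (nucleotide rows, length 3x protein
#'   columns).
#' @export
codon_backtranslate <- function(protein_msa, cds_by_id) {
  miss <- setdiff(protein_msa$ids, names(cds_by_id))
  if (length(miss)) stop("no CDS for: ", paste(miss, collapse = ", "))
  rows <- vapply(protein_msa$ids, function(id) {
    aa_row <- strsplit(protein_msa$rows[[id]], "")[[1]]
    cds <- toupper(cds_by_id[[id]])
    if (nchar(cds) %% 3L != 0L)
      stop("CDS length of ", id, " is not a multiple of 3")
    codons <- .split_codons(cds)
    if (length(codons) > 1L && .is_stop(codons[length(codons)]))
      codons <- codons[-length(codons)]
    aa_expect <- .codon_aa(codons)
    aa_have <- aa_row[aa_row != "-"]
    if (length(aa_have) != length(codons) || !all(aa_have == aa_expect)) {
      bad <- which(aa_have != aa_expect[seq_along(aa_have)])[1]
      stop("protein row of ", id, " does not match its CDS translation",
           if (!is.na(bad)) paste0(" at residue ", bad) else
             " (length mismatch)")
    }
    out <- rep("---", length(aa_row))
    out[aa_row != "-"] <- codons
    paste(out, collapse = "")
  }, character(1))
  .new_alignment(protein_msa$ids, unname(rows))
}
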