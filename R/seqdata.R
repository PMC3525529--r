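# DEFL peptide characterisation: mature peptides, cysteine scaffolds, and
# loss-of-function (pseudogene) classification against a family consensus.

#' Extract the mature peptide
#'
#' Removes the signal peptide: the mature peptide is the suffix starting at
#' residue `cleavage_index + 1`. Cleavage positions are inputs (e.g. from an
#' external signal-peptide predictor); they are not predicted here.
#'
#' @param protein Amino-acid string.
#' @param cleavage_index Number of residues in the signal peptide
#'   (`0 <= cleavage_index < nchar(protein)`); 0 returns the whole protein.
#' @return The mature peptide string.
#' @export
mature_peptide <- function(protein, cleavage_index) {
  stopifnot(is.character(protein), length(protein) == 1L)
  n <- nchar(protein)
  if (is.na(cleavage_index) || cleavage_index < 0 || cleavage_index >= n)
    stop("cleavage_index must be in [0, nchar(protein) - 1]")
  substr(protein, cleavage_index + 1L, n)
}

#' Cysteine scaffold of a peptide
#'
#' Counts cysteines and tests for the C-terminal CXC motif characteristic
#' of LURE-type defensin-like peptides: a `C-x-C` whose last cysteine lies
#' within the final `terminal_window` residues.
#'
#' @param peptide Amino-acid string (non-empty).
#' @param terminal_window Size of the C-terminal window in which the last
#'   cysteine of the motif must fall (default 3).
#' @return A list with `count`, `positions` (1-based, increasing) and
#'   `cxc_terminal`.
#' @export
cysteine_profile <- function(peptide, terminal_window = 3L) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nchar(peptide) > 0L)
  peptide <- toupper(peptide)
  res <- strsplit(peptide, "")[[1]]
  pos <- which(res == "C")
  n <- length(res)
  cxc <- FALSE
  if (length(pos) >= 2L) {
    # positions i, i+2 both C with i+2 inside the terminal window
    cxc <- any(pos + 2L >= n - terminal_window + 1L &
               (pos + 2L) %in% pos &
               pos + 2L <= n)
  }
  list(count = length(pos), positions = pos, cxc_terminal = cxc)
}

#' Family consensus for integrity checks
#'
#' Builds, from at least two intact family members, (i) a majority-rule
#' consensus CDS from a progressive nucleotide alignment and (ii) the set of
#' conserved cysteine positions, defined as protein-alignment columns where
#' at least `cys_threshold` of the members carry a cysteine, expressed in
#' consensus-protein coordinates.
#'
#' @param cds_list Named character vector/list of intact member CDSs.
#' @param cys_threshold Fraction of members that must carry C for a column
#'   to be called a conserved cysteine (default 0.8; the threshold is a
#'   package choice and is echoed in the result).
#' @return An object of class `family_consensus` with elements `cds`,
#'   `protein`, `conserved_cys` (1-based consensus-protein positions),
#'   `cys_threshold`, `n_members`.
#' @export
family_consensus <- function(cds_list, cys_threshold = 0.8) {
  cds_list <- unlist(as.list(cds_list))
  if (length(cds_list) < 2L)
    stop("family consensus needs at least 2 intact members")
  if (is.null(names(cds_list)) || any(names(cds_list) == ""))
    stop("members must be named")

  nt_msa <- progressive_msa(toupper(cds_list), scoring_params("NUC"))
  cons_cds <- .msa_consensus(nt_msa$rows)

  prots <- vapply(cds_list, .translate_orf, character(1))
  if (any(nchar(prots) == 0L)) stop("a member translates to an empty protein")
  aa_msa <- progressive_msa(prots, scoring_params("BLOSUM62"))
  rows <- do.call(rbind, strsplit(unname(aa_msa$rows), ""))
  frac_c <- colMeans(rows == "C")
  keep <- colMeans(rows != "-") >= 0.5 # consensus keeps majority-occupied columns
  cons_prot_res <- apply(rows[, keep, drop = FALSE], 2, function(col) {
    col <- col[col != "-"]
    names(sort(table(col), decreasing = TRUE))[1]
  })
  cons_positions <- cumsum(keep)
  conserved <- sort(unique(cons_positions[frac_c >= cys_threshold & keep]))

  structure(
    list(cds = cons_cds, protein = paste(cons_prot_res, collapse = ""),
         conserved_cys = conserved, cys_threshold = cys_threshold,
         n_members = length(cds_list)),
    class = "family_consensus"
  )
}

# majority-rule consensus of gapped rows; columns with <50% occupancy dropped
.msa_consensus <- function(rows) {
  m <- do.call(rbind, strsplit(unname(rows), ""))
  keep <- colMeans(m != "-") >= 0.5
  res <- apply(m[, keep, drop = FALSE], 2, function(col) {
    col <- col[col != "-"]
    names(sort(table(col), decreasing = TRUE))[1]
  })
  paste(res, collapse = "")
}

#' Integrity / loss-of-function report for a family member
#'
#' Classifies one gene against its family consensus. Frameshifts are
#' detected from a global nucleotide alignment to the consensus CDS: any
#' insertion or deletion run whose length is not a multiple of 3, downstream
#' of the start codon, disrupts the reading frame. The reported position is
#' the 1-based consensus nucleotide index of the first such indel column.
#' Premature stops come from translating the CDS in its annotated frame;
#' cysteine loss is any conserved cysteine column holding a non-C residue.
#'
#' @param record A [gene_record()] (or a list with `cds`, `protein`,
#'   optionally `cleavage_index`, `id`).
#' @param consensus A [family_consensus()] object.
#' @param params_nuc,params_prot Scoring parameters for the nucleotide and
#'   protein alignments (sensible defaults).
#' @return An object of class `integrity_report`: flags `premature_stop`
#'   (+ codon), `frameshift` (+ first consensus nucleotide position),
#'   `cysteine_loss` (+ data frame of consensus position / observed
#'   residue), `cxc_terminal`, and `verdict` (`"intact"` or
#'   `"putative_loss_of_function"`).
#' @export
integrity_report <- function(record, consensus,
                             params_nuc = scoring_params("NUC"),
                             params_prot = scoring_params("BLOSUM62")) {
  if (!inherits(consensus, "family_consensus"))
    stop("'consensus' must be a family_consensus object")
  if (is.null(consensus$cds) || nchar(consensus$cds) == 0L)
    stop("consensus CDS is empty")
  cds <- toupper(record$cds)

  # frameshift: indel runs vs consensus with length %% 3 != 0
  aln <- global_align(c(query = cds, consensus = consensus$cds), params_nuc)
  qa <- strsplit(aln$rows[["query"]], "")[[1]]
  ca <- strsplit(aln$rows[["consensus"]], "")[[1]]
  cons_pos <- cumsum(ca != "-") # consensus coordinate at each column
  indel <- (qa == "-") | (ca == "-")
  frameshift <- FALSE
  fs_pos <- NA_integer_
  if (any(indel)) {
    runs <- rle(indel)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      len <- runs$lengths[k]
      col1 <- starts[k]
      # consensus coordinate of the first indel column (next consensus base
      # for an insertion into the query)
      p <- if (ca[col1] == "-") cons_pos[col1] + 1L else cons_pos[col1]
      if (len %% 3L != 0L && p > 3L) { # downstream of the start codon
        frameshift <- TRUE
        fs_pos <- p
        break
      }
    }
  }

  tr <- suppressWarnings(translate_cds(cds))
  premature <- tr$premature_stop

  # conserved-cysteine check on the protein vs the consensus protein
  cys_changes <- data.frame(consensus_pos = integer(0),
                            observed = character(0))
  protein <- record$protein
  if (is.null(protein) || nchar(protein) == 0L)
    protein <- suppressWarnings(.translate_orf(cds))
  if (length(consensus$conserved_cys) && nchar(protein) > 0L) {
    pal <- global_align(c(query = protein, consensus = consensus$protein),
                        params_prot)
    qp <- strsplit(pal$rows[["query"]], "")[[1]]
    cp <- strsplit(pal$rows[["consensus"]], "")[[1]]
    ppos <- cumsum(cp != "-")
    for (cpos in consensus$conserved_cys) {
      col <- which(ppos == cpos & cp != "-")[1]
      obs <- if (is.na(col)) "-" else qp[col]
      if (!identical(obs, "C")) {
        cys_changes <- rbind(cys_changes,
                             data.frame(consensus_pos = cpos, observed = obs))
      }
    }
  }
  cys_loss <- nrow(cys_changes) > 0L

  cxc <- if (!is.null(record$cleavage_index) && !is.na(record$cleavage_index) &&
             record$cleavage_index > 0 &&
             record$cleavage_index < nchar(protein)) {
    cysteine_profile(mature_peptide(protein, record$cleavage_index))$cxc_terminal
  } else if (nchar(protein) > 0L) {
    cysteine_profile(protein)$cxc_terminal
  } else FALSE

  verdict <- if (premature || frameshift || cys_loss)
    "putative_loss_of_function" else "intact"

  structure(
    list(id = record$id %||% NA_character_,
         premature_stop = premature,
         premature_stop_codon = tr$premature_stop_codon,
         frameshift = frameshift, frameshift_position = fs_pos,
         cysteine_loss = cys_loss, cysteine_changes = cys_changes,
         cxc_terminal = cxc, verdict = verdict,
         cys_threshold = consensus$cys_threshold),
    class = "integrity_report"
  )
}

#' @export
print.integrity_report <- function(x, ...) {
  cat(sprintf("<integrity_report> %s: %s\n", x$id, x$verdict))
  if (x$frameshift)
    cat(sprintf("  frameshift at consensus nucleotide %d\n",
                x$frameshift_position))
  if (x$premature_stop)
    cat(sprintf("  premature stop at codon %d\n", x$premature_stop_codon))
  if (x$cysteine_loss)
    cat(sprintf("  conserved cysteine(s) lost at %s\n",
                paste(x$cysteine_changes$consensus_pos, collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
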