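# Checks anchored on the published AtLURE1 (CRP810_1) accessions. These
# need the TAIR coding sequences, which are not distributed with the
# package; supply them as a FASTA and this function reproduces the
# family's printed sequence facts.

#' Sequence-fact checks for a user-supplied AtLURE1 CDS FASTA
#'
#' Given the coding sequences of the five intact family members and the
#' pseudogene (TAIR accessions At5g43285, At5g43510, At5g43513,
#' At5g43518, At5g43525 and At5g43516), computes (i) all pairwise
#' full-length protein identities among the intact members, (ii) pairwise
#' NG86 dN/dS of the putative ancestral copy versus the others, (iii) the
#' cysteine count of each mature peptide, and (iv) the integrity report of
#' the pseudogene against the family consensus (expected: frameshift at
#' consensus nucleotide 17).
#'
#' @param fasta Path to a CDS FASTA, or a named character vector.
#' @param intact_ids Ids of the intact members, ancestral copy first.
#' @param pseudo_id Id of the pseudogene record (optional, `NA` to skip).
#' @param cleavage_index Signal-peptide length used for the mature
#'   peptides (residues; single value recycled).
#' @return List with `identity` (pairwise percent-identity matrix),
#'   `dnds` (data frame, ancestral copy vs each other member),
#'   `cysteines` (mature-peptide cysteine count per intact member) and
#'   `pseudogene` (an `integrity_report`, or `NULL`).
#' @export
atlure_anchor_checks <- function(fasta,
                                 intact_ids = paste0("AtLURE1.", 1:5),
                                 pseudo_id = "AtLURE1.6",
                                 cleavage_index = 24L) {
  cds <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_fasta(fasta) else unlist(as.list(fasta))
  miss <- setdiff(intact_ids, names(cds))
  if (length(miss))
    stop("FASTA lacks records: ", paste(miss, collapse = ", "))

  prots <- vapply(cds[intact_ids], .translate_orf, character(1))
  aa_msa <- progressive_msa(prots, scoring_params("BLOSUM62"))
  n <- length(intact_ids)
  idm <- matrix(NA_real_, n, n, dimnames = list(intact_ids, intact_ids))
  for (ij in combn(n, 2, simplify = FALSE)) {
    pid <- percent_identity(aa_msa, intact_ids[ij])
    idm[ij[1], ij[2]] <- idm[ij[2], ij[1]] <- pid
  }

  codon_msa <- codon_backtranslate(aa_msa, cds[intact_ids])
  anc <- intact_ids[1]
  dnds <- do.call(rbind, lapply(intact_ids[-1], function(id) {
    st <- ng86_pairwise(codon_msa$rows[[anc]], codon_msa$rows[[id]])
    data.frame(pair = paste(anc, id, sep = " vs "), dN = st$dN, dS = st$dS,
               omega = st$omega, dS_zero = st$flags$dS_zero)
  }))

  cys <- vapply(prots, function(p)
    cysteine_profile(mature_peptide(p, min(cleavage_index,
                                           nchar(p) - 1L)))$count,
    integer(1))

  pseudo <- NULL
  if (!is.na(pseudo_id) && pseudo_id %in% names(cds)) {
    consensus <- family_consensus(cds[intact_ids])
    rec <- list(id = pseudo_id, cds = cds[[pseudo_id]],
                protein = NULL, cleavage_index = NA_integer_)
    pseudo <- integrity_report(rec, consensus)
  }
  list(identity = idm, dnds = dnds, cysteines = cys, pseudogene = pseudo)
}
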