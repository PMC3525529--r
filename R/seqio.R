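# Sequence and gene-table I/O plus the GeneRecord container.

#' Read a FASTA file
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' Records are wrapped at 60 columns.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read a gene-order table
#'
#' Tab-separated with columns `species`, `gene_id`, `scaffold`, `start`,
#' `end`, `strand`; coordinates 1-based inclusive.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with those columns, checked for validity.
#' @export
read_gene_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_gene_table(tab)
}

#' @rdname read_gene_table
#' @param tab A gene-table `data.frame`.
#' @export
validate_gene_table <- function(tab) {
  need <- c("species", "gene_id", "scaffold", "start", "end", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("gene table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in gene table: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  if (any(tab$start > tab$end)) stop("gene table has start > end")
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tab[need]
}

#' Write a gene-order table
#'
#' @param tab A gene-table `data.frame` (see [read_gene_table()]).
#' @param path Output path.
#' @export
write_gene_table <- function(tab, path) {
  write.table(validate_gene_table(tab), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene record
#'
#' Bundles one gene's coordinates and sequences. If `protein` is omitted it
#' is derived by translating the CDS up to the first stop codon.
#'
#' @param id,species,scaffold Identifiers.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param cds Nucleotide coding sequence (alphabet `A,C,G,T,N`).
#' @param protein Optional amino-acid sequence.
#' @param cleavage_index Optional number of signal-peptide residues removed
#'   by cleavage (the mature peptide starts at `cleavage_index + 1`).
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(id, species, scaffold, start, end, strand, cds,
                        protein = NULL, cleavage_index = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0L)
  if (start > end) stop("start must be <= end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds)) stop("cds alphabet must be within {A,C,G,T,N}")
  if (is.null(protein)) {
    protein <- if (nchar(cds) >= 3L) .translate_orf(cds) else ""
  } else if (nchar(cds) %% 3L == 0L) {
    expect <- .translate_orf(cds)
    if (!identical(toupper(protein), expect))
      stop("protein does not equal the translation of cds up to the first ",
           "stop for gene ", id)
    protein <- toupper(protein)
  }
  structure(
    list(id = id, species = species, scaffold = scaffold,
         start = as.integer(start), end = as.integer(end), strand = strand,
         cds = cds, protein = protein,
         cleavage_index = as.integer(cleavage_index)),
    class = "gene_record"
  )
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s (%s) %s:%d-%d(%s), CDS %d nt, protein %d aa\n",
              x$id, x$species, x$scaffold, x$start, x$end, x$strand,
              nchar(x$cds), nchar(x$protein)))
  invisible(x)
}
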