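# Sequence-level building blocks shared by all stages: the coding_region
# container, the genetic code, and FASTA I/O.

#' @importFrom Biostrings GENETIC_CODE DNAStringSet readDNAStringSet
#'   writeXStringSet
NULL

#' The 20 standard amino acids (single-letter codes, alphabetical)
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Positively / negatively charged amino-acid classes
#'
#' Lysine, arginine and histidine carry a positive side-chain charge;
#' glutamate and aspartate a negative one. These are the composite target
#' sets of the charged-class enrichment tests.
#' @keywords internal
CHARGE_CLASSES <- list(positive = c("K", "R", "H"),
                       negative = c("E", "D"))

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons (DNA alphabet)
#' @keywords internal
sense_codons <- function() {
  all <- names(Biostrings::GENETIC_CODE)
  all[!all %in% STOP_CODONS]
}

split_codons <- function(sequence) {
  n <- nchar(sequence) %/% 3L
  substring(sequence, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' A gene's coding sequence with derived codon and protein views
#'
#' Bundles one CDS (frame 0, DNA alphabet, optionally ending in a stop codon)
#' with its codon decomposition and translation. The protein excludes the
#' terminal stop; internal stops are not allowed.
#'
#' @param gene_id Gene identifier.
#' @param sequence CDS nucleotide sequence (character scalar, A/C/G/T,
#'   length a multiple of 3).
#' @return An object of class `coding_region`: a list with elements
#'   `gene_id`, `sequence`, `codons` (character vector), `protein`
#'   (character vector of single-letter amino acids, one per sense codon)
#'   and `n_codons` (number of codons including a terminal stop if present).
#' @examples
#' cr <- coding_region("g1", "ATGAAACCCTAA")
#' cr$protein  # "M" "K" "P"
#' @export
coding_region <- function(gene_id, sequence) {
  sequence <- toupper(gsub("U", "T", as.character(sequence)))
  if (nchar(sequence) %% 3L != 0L)
    stop("CDS length of ", gene_id, " is not a multiple of 3")
  codons <- split_codons(sequence)
  aa <- translate_codons(codons)
  internal_stop <- which(aa == "*")
  internal_stop <- internal_stop[internal_stop < length(aa)]
  if (length(internal_stop))
    stop("internal stop codon in ", gene_id, " at codon ",
         internal_stop[1L])
  protein <- aa[aa != "*"]
  structure(list(gene_id = gene_id, sequence = sequence, codons = codons,
                 protein = protein, n_codons = length(codons)),
            class = "coding_region")
}

#' @export
print.coding_region <- function(x, ...) {
  cat("<coding_region>", x$gene_id, "-", x$n_codons, "codons\n")
  invisible(x)
}

# Integer-encoded protein (index into AA_ALPHABET, NA for stop) over all
# codon positions; used by the permutation machinery for fast window lookups.
protein_index <- function(gene) {
  match(translate_codons(gene$codons), AA_ALPHABET)
}

#' Read coding sequences from a FASTA file
#'
#' One record per gene; record names become gene ids (text after the first
#' whitespace is dropped).
#'
#' @param path FASTA file path.
#' @return Named list of [coding_region()] objects.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  genes <- lapply(seq_along(seqs),
                  function(i) coding_region(ids[i], as.character(seqs[[i]])))
  names(genes) <- ids
  genes
}

#' Write coding sequences to a FASTA file
#'
#' @param genes Named list of [coding_region()] objects.
#' @param path Output FASTA path.
#' @export
write_cds_fasta <- function(genes, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genes, `[[`, "", "gene_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
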