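#' Round half away from zero
#'
#' Report-style rounding (4.5 -> 5), as used for the percentage and frequency
#' tables, in contrast to R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Reverse complement of an uppercase DNA string (delegates to Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a DNA string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Write tRNA gene records to FASTA
#'
#' Headers follow `accession|species|gene`.
#'
#' @param records Data frame of gene records (see [extract_trna_genes()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  seqs <- Biostrings::DNAStringSet(records$sequence)
  names(seqs) <- paste(records$accession, records$species, records$gene,
                       sep = "|")
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a gene FASTA written by [write_gene_fasta()]
#'
#' @param path FASTA file path.
#' @return Data frame with `accession`, `species`, `gene`, `sequence`.
#' @export
read_gene_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  data.frame(
    accession = vapply(parts, `[`, "", 1L),
    species = vapply(parts, `[`, "", 2L),
    gene = vapply(parts, `[`, "", 3L),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
}
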