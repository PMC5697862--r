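#' Reference mt-tRNA gene registry
#'
#' Coordinates of the 22 mitochondrial tRNA genes on the revised Cambridge
#' Reference Sequence (rCRS, NC_012920.1), 1-based inclusive, with coding
#' strand. All genome positions used by this package refer to rCRS positions;
#' per-species coordinates are recovered through gene-relative (molecule)
#' positions.
#'
#' @return A data.frame with columns `gene`, `start`, `end`, `strand`,
#'   `length`.
#' @export
rcrs_gene_table <- function() {
  df <- data.frame(
    gene = c("tRNA-Phe", "tRNA-Val", "tRNA-Leu(UUR)", "tRNA-Ile", "tRNA-Gln",
             "tRNA-Met", "tRNA-Trp", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys",
             "tRNA-Tyr", "tRNA-Ser(UCN)", "tRNA-Asp", "tRNA-Lys", "tRNA-Gly",
             "tRNA-Arg", "tRNA-His", "tRNA-Ser(AGY)", "tRNA-Leu(CUN)",
             "tRNA-Glu", "tRNA-Thr", "tRNA-Pro"),
    start = c(577L, 1602L, 3230L, 4263L, 4329L, 4402L, 5512L, 5587L, 5657L,
              5761L, 5826L, 7446L, 7518L, 8295L, 9991L, 10405L, 12138L,
              12207L, 12266L, 14674L, 15888L, 15956L),
    end = c(647L, 1670L, 3304L, 4331L, 4400L, 4469L, 5579L, 5655L, 5729L,
            5826L, 5891L, 7514L, 7585L, 8364L, 10058L, 10469L, 12206L,
            12265L, 12336L, 14742L, 15953L, 16023L),
    strand = c("+", "+", "+", "+", "-", "+", "+", "-", "-", "-", "-", "-",
               "+", "+", "+", "+", "+", "+", "+", "-", "+", "-"),
    stringsAsFactors = FALSE
  )
  df$length <- df$end - df$start + 1L
  df
}

#' rCRS mt-tRNA-Leu(UUR) gene sequence
#'
#' The 75-nt tRNA-Leu(UUR) gene of the rCRS (positions 3230..3304, heavy
#' strand). Position 14 of this molecule is rCRS 3243, the site of the MELAS
#' mutation m.3243A>G.
#'
#' @return Single uppercase DNA string.
#' @export
rcrs_leu_uur <- function() {
  "GTTAAGATGGCAGAGCCCGGTAATCGCATAAAACTTAAAACTTTACAGTCAGAGGTTCAATTCCTCTTCTTAACA"
}

#' Reference sequences for the duplicated Leu/Ser paralog pairs
#'
#' mtDNA carries two tRNA-Leu and two tRNA-Ser genes; extracted records
#' labelled only "tRNA-Leu" or "tRNA-Ser" must be assigned to a paralog by
#' percent identity against these references. The Leu(UUR) entry is the true
#' rCRS gene; the other three are synthetic rCRS-like stand-in sequences
#' (documented as such) that differ from their paralog partner at many sites,
#' which is all the disambiguation step requires.
#'
#' @return Named character vector of DNA strings.
#' @export
paralog_references <- function() {
  c(
    "tRNA-Leu(UUR)" = rcrs_leu_uur(),
    # synthetic stand-ins below (rCRS-like composition, not the true genes)
    "tRNA-Leu(CUN)" = "ACTTTTAAAGGATAACAGCTATCCATTGGTCTTAGGCCCCAAAAATTTTGGTGCAACTCCAAATAAAAGTA",
    "tRNA-Ser(UCN)" = "GAAAAAGTCATGGAGGCCATGGGGTTGGCTTGAAACCAGCTTTGGGGGGTTCGATTCCTTCCTTTTTTG",
    "tRNA-Ser(AGY)" = "GAGAAAGCTCACAAGAACTGCTAACTCATGCCCCCATGTCTAACAACATGGCTTTCTCA"
  )
}

# Canonical product-label normalization. Keys are upper-cased, stripped of
# spaces/underscores/parentheses content variants seen in GenBank records.
.product_map <- function() {
  c(
    "TRNA-PHE" = "tRNA-Phe", "TRNF" = "tRNA-Phe", "TRNA-VAL" = "tRNA-Val",
    "TRNV" = "tRNA-Val", "TRNA-LEU(UUR)" = "tRNA-Leu(UUR)",
    "TRNA-LEU(TAA)" = "tRNA-Leu(UUR)", "TRNL1" = "tRNA-Leu(UUR)",
    "TRNA-LEU(CUN)" = "tRNA-Leu(CUN)", "TRNA-LEU(TAG)" = "tRNA-Leu(CUN)",
    "TRNL2" = "tRNA-Leu(CUN)", "TRNA-LEU" = "tRNA-Leu",
    "TRNA-ILE" = "tRNA-Ile", "TRNA-GLN" = "tRNA-Gln", "TRNA-MET" = "tRNA-Met",
    "TRNA-TRP" = "tRNA-Trp", "TRNA-ALA" = "tRNA-Ala", "TRNA-ASN" = "tRNA-Asn",
    "TRNA-CYS" = "tRNA-Cys", "TRNA-TYR" = "tRNA-Tyr",
    "TRNA-SER(UCN)" = "tRNA-Ser(UCN)", "TRNA-SER(TGA)" = "tRNA-Ser(UCN)",
    "TRNS1" = "tRNA-Ser(UCN)", "TRNA-SER(AGY)" = "tRNA-Ser(AGY)",
    "TRNA-SER(GCT)" = "tRNA-Ser(AGY)", "TRNS2" = "tRNA-Ser(AGY)",
    "TRNA-SER" = "tRNA-Ser", "TRNA-ASP" = "tRNA-Asp", "TRNA-LYS" = "tRNA-Lys",
    "TRNA-GLY" = "tRNA-Gly", "TRNA-ARG" = "tRNA-Arg", "TRNA-HIS" = "tRNA-His",
    "TRNA-GLU" = "tRNA-Glu", "TRNA-THR" = "tRNA-Thr", "TRNA-PRO" = "tRNA-Pro"
  )
}

#' Normalize a GenBank tRNA product label to a canonical gene name
#'
#' Labels are matched case-insensitively after collapsing whitespace (so
#' "tRNA-Leu (UUR)" and "tRNA-Leu(UUR)" agree). Ambiguous labels
#' ("tRNA-Leu", "tRNA-Ser") are returned as-is for paralog disambiguation;
#' unknown labels return `NA` so callers can route them to a review bucket
#' rather than guess.
#'
#' @param label Product qualifier string from a GenBank feature.
#' @return Canonical gene name, `"tRNA-Leu"`/`"tRNA-Ser"` for ambiguous
#'   paralogs, or `NA_character_` if unrecognized.
#' @export
normalize_product <- function(label) {
  key <- toupper(gsub("[[:space:]]+", "", label))
  map <- .product_map()
  out <- unname(map[key])
  out
}

#' Convert an rCRS genome position to a position within a tRNA molecule
#'
#' For heavy(plus)-strand genes the molecule position is the 1-based offset
#' from the gene start; light-strand genes read in the opposite orientation,
#' so the offset is counted from the gene end. E.g. rCRS 3243 is position 14
#' of mt-tRNA-Leu(UUR).
#'
#' @param rcrs_pos Integer rCRS position (1-based).
#' @param gene Canonical gene name present in [rcrs_gene_table()].
#' @return Integer molecule position (1-based).
#' @export
molecule_position <- function(rcrs_pos, gene) {
  tab <- rcrs_gene_table()
  row <- tab[tab$gene == gene, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown gene: ", gene)
  }
  if (any(rcrs_pos < row$start | rcrs_pos > row$end)) {
    stop(sprintf("rCRS position %s outside %s interval [%d..%d]",
                 paste(rcrs_pos[rcrs_pos < row$start | rcrs_pos > row$end],
                       collapse = ","),
                 gene, row$start, row$end))
  }
  if (row$strand == "+") {
    as.integer(rcrs_pos - row$start + 1L)
  } else {
    as.integer(row$end - rcrs_pos + 1L)
  }
}
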