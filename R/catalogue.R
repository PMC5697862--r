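REGION_LABELS <- c("acc-stem", "d-stem", "d-loop", "ac-stem", "ac-loop",
                   "variable", "t-stem", "t-loop")
PATHO_CLASSES <- c("neutral", "possibly", "probably", "definitely")

#' Load a disease-associated variant catalogue
#'
#' Reads a CSV/TSV catalogue of mt-tRNA variants with columns
#' `position` (rCRS, 1-based), `ref`, `alt` (single IUPAC base or `-` for a
#' deletion), `gene`, `region`, `class` and optional `tertiary` (a
#' `"(8-14)-21"`-style molecule-position triple). Entries are validated
#' (alleles, gene span, region labels, duplicates), given their molecule
#' position and returned sorted by rCRS position.
#'
#' @param path Path to the catalogue file (delimiter inferred from the
#'   extension: `.tsv` tab, otherwise comma).
#' @param template Optional [cloverleaf_template()] used to cross-check each
#'   entry's region label against the template at its molecule position.
#' @return Data frame of validated entries with a `molecule_position` column.
#' @export
load_catalogue <- function(path, template = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "\"")
  required <- c("position", "ref", "alt", "gene", "region", "class")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("catalogue is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!nrow(df)) {
    df$molecule_position <- integer(0)
    return(df)
  }
  if (!("tertiary" %in% names(df))) df$tertiary <- NA_character_
  genes <- rcrs_gene_table()
  bases <- c("A", "C", "G", "T", "-")
  for (i in seq_len(nrow(df))) {
    row_id <- sprintf("catalogue row %d (position %s)", i, df$position[i])
    if (!(df$ref[i] %in% bases) || !(df$alt[i] %in% bases)) {
      stop(row_id, ": malformed allele '", df$ref[i], ">", df$alt[i], "'")
    }
    if (df$ref[i] == df$alt[i]) {
      stop(row_id, ": ref and alt alleles are identical")
    }
    g <- genes[genes$gene == df$gene[i], , drop = FALSE]
    if (nrow(g) != 1L) stop(row_id, ": unknown gene '", df$gene[i], "'")
    if (df$position[i] < g$start || df$position[i] > g$end) {
      stop(row_id, ": position outside the ", df$gene[i],
           " span [", g$start, "..", g$end, "]")
    }
    if (!(df$region[i] %in% REGION_LABELS)) {
      stop(row_id, ": unknown region label '", df$region[i], "'")
    }
    if (!(df$class[i] %in% PATHO_CLASSES)) {
      stop(row_id, ": unknown pathogenicity class '", df$class[i], "'")
    }
  }
  key <- paste(df$position, df$ref, df$alt)
  if (anyDuplicated(key)) {
    stop("duplicate catalogue entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  df$molecule_position <- vapply(seq_len(nrow(df)), function(i) {
    molecule_position(df$position[i], df$gene[i])
  }, 1L)
  if (!is.null(template)) {
    for (i in seq_len(nrow(df))) {
      if (df$gene[i] != template$gene) next
      treg <- region_of_position(template, df$molecule_position[i])
      if (!is.na(treg) && treg != df$region[i]) {
        stop(sprintf(
          "catalogue row %d: region '%s' inconsistent with template ('%s' at molecule position %d)",
          i, df$region[i], treg, df$molecule_position[i]))
      }
    }
  }
  df <- df[order(df$position, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Path to the packaged mt-tRNA-Leu(UUR) variant catalogue
#'
#' 32 disease-associated entries for tRNA-Leu(UUR). The positions and classes
#' of the screened variants discussed in the package documentation are
#' literature values; the remainder of the 32 rows are realistic synthetic
#' entries (see the file header) so the packaged evidence table reproduces a
#' 12 neutral / 8 possibly / 1 probably / 11 definitely split.
#'
#' @return File path.
#' @export
leu_catalogue_path <- function() {
  system.file("extdata", "leu_uur_catalogue.csv", package = "mttrnascreen",
              mustWork = TRUE)
}

#' Path to the packaged per-variant pathogenicity evidence table
#' @return File path.
#' @export
leu_evidence_path <- function() {
  system.file("extdata", "leu_uur_evidence.csv", package = "mttrnascreen",
              mustWork = TRUE)
}
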