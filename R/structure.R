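#' Load a cloverleaf secondary-structure template
#'
#' A template fixes, per gene, the molecule-position intervals of the four
#' stems (acceptor, D, anticodon, T) and their loops/variable region, the
#' stem partner map (an involution pairing each 5' position with its 3'
#' partner), and the long-range tertiary interaction triples. The packaged
#' default is the mt-tRNA-Leu(UUR) template: its D-stem pairs positions
#' 10..13 with 27..24, the register under which the reference molecule shows
#' two Watson-Crick pairs, one mismatch (two unpaired nucleotides) and a G-U
#' wobble adjacent to the D-loop, and under which 3253T>C / 3254C>T /
#' 3256C>T have their described effects.
#'
#' @param path YAML template file; default is the packaged Leu(UUR) template.
#' @return Object of class `mt_cloverleaf` with fields `gene`, `reference`,
#'   `length`, `region` (per-position labels, `NA` for connector positions),
#'   `partner` (per-position partner, `NA` if unpaired), `pairs` (data frame
#'   `pos5`, `pos3`, `region`), `tertiary` (list of position vectors).
#' @export
cloverleaf_template <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cloverleaf_leu_uur.yaml",
                        package = "mttrnascreen", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  n <- nchar(cfg$reference)
  region <- rep(NA_character_, n)
  for (rg in names(cfg$regions)) {
    for (iv in cfg$regions[[rg]]) {
      span <- iv[[1]]:iv[[2]]
      if (any(!is.na(region[span]))) {
        stop("template regions overlap at positions ",
             paste(span[!is.na(region[span])], collapse = ","))
      }
      region[span] <- rg
    }
  }
  pairs <- do.call(rbind, lapply(cfg$pairs, function(p) {
    data.frame(pos5 = p[[1]], pos3 = p[[2]], stringsAsFactors = FALSE)
  }))
  pairs$region <- region[pairs$pos5]
  partner <- rep(NA_integer_, n)
  partner[pairs$pos5] <- pairs$pos3
  partner[pairs$pos3] <- pairs$pos5
  # involution check
  paired <- which(!is.na(partner))
  if (!all(partner[partner[paired]] == paired)) {
    stop("template partner map is not an involution")
  }
  if (any(region[pairs$pos5] != region[pairs$pos3])) {
    stop("paired positions must lie in the same stem")
  }
  tertiary <- lapply(cfg$tertiary, function(x) as.integer(unlist(x)))
  structure(list(gene = cfg$gene, reference = toupper(cfg$reference),
                 length = n, region = region, partner = partner,
                 pairs = pairs, tertiary = tertiary),
            class = "mt_cloverleaf")
}

#' Region label of a molecule position under a template
#'
#' @param template [cloverleaf_template()].
#' @param pos Molecule position(s).
#' @return Region label(s); `NA` for connector positions outside the named
#'   domains.
#' @export
region_of_position <- function(template, pos) {
  stopifnot(inherits(template, "mt_cloverleaf"))
  template$region[pos]
}

#' Classify a stem base pair
#'
#' `A:T`/`T:A`/`G:C`/`C:G` are Watson-Crick; `G:T`/`T:G` is the wobble pair
#' (G-U in the RNA); anything else over `A,C,G,T` is a mismatch, i.e. two
#' unpaired nucleotides facing each other in the stem. `N` or a gap gives
#' `"unknown"` and is excluded from tallies.
#'
#' @param b5,b3 Bases at the 5' and 3' side of the pair.
#' @return One of `"watson_crick"`, `"wobble"`, `"mismatch"`, `"unknown"`.
#' @export
pair_class <- function(b5, b3) {
  key <- paste0(b5, b3)
  if (b5 %in% c("N", "-") || b3 %in% c("N", "-") ||
      !(b5 %in% c("A", "C", "G", "T")) || !(b3 %in% c("A", "C", "G", "T"))) {
    return("unknown")
  }
  if (key %in% c("AT", "TA", "GC", "CG")) return("watson_crick")
  if (key %in% c("GT", "TG")) return("wobble")
  "mismatch"
}

# Map a sequence onto template coordinates: returns a character vector of
# length template$length with the member base at each template position
# ("-"/NA where the member has a gap). Sequences that are not a gap-free
# exact-length match are anchored-aligned to the template reference first;
# template positions falling in member gaps stay unknown rather than being
# shifted.
template_bases <- function(seq, template) {
  seq <- toupper(seq)
  if (nchar(seq) == template$length && !grepl("-", seq, fixed = TRUE)) {
    return(seq_chars(seq))
  }
  msa <- anchor_msa(template$reference, c(member = gsub("-", "", seq,
                                                        fixed = TRUE)))
  row <- seq_chars(msa$rows[["member"]])
  row[msa$column_of_rcrs]
}

#' Annotate every stem pair of a gene sequence
#'
#' @param seq Gene sequence in molecule orientation (may contain indels
#'   relative to the template; it is then anchored to the template
#'   reference, and template positions that fall in gaps are annotated
#'   `"unknown"`).
#' @param template [cloverleaf_template()].
#' @return Data frame with `pos5`, `pos3`, `region`, `base5`, `base3`,
#'   `pair_class`.
#' @export
annotate_cloverleaf <- function(seq, template) {
  stopifnot(inherits(template, "mt_cloverleaf"))
  if (abs(nchar(gsub("-", "", seq, fixed = TRUE)) - template$length) > 5) {
    warning("sequence length differs from the template by more than 5 nt; ",
            "annotation may not be meaningful")
  }
  bases <- template_bases(seq, template)
  ann <- template$pairs
  ann$base5 <- bases[ann$pos5]
  ann$base3 <- bases[ann$pos3]
  ann$pair_class <- vapply(seq_len(nrow(ann)), function(i) {
    pair_class(ann$base5[i], ann$base3[i])
  }, "")
  ann
}

#' Summarize pair classes within one stem
#'
#' @param annotation Output of [annotate_cloverleaf()].
#' @param region Stem region label, e.g. `"d-stem"`.
#' @return Named integer vector of pair-class counts, plus
#'   `unpaired_nucleotides` (= 2 per mismatch pair).
#' @export
stem_report <- function(annotation, region) {
  sub <- annotation[annotation$region == region, , drop = FALSE]
  counts <- c(watson_crick = sum(sub$pair_class == "watson_crick"),
              wobble = sum(sub$pair_class == "wobble"),
              mismatch = sum(sub$pair_class == "mismatch"),
              unknown = sum(sub$pair_class == "unknown"))
  c(counts, unpaired_nucleotides = 2L * counts[["mismatch"]])
}

# apply a catalogue variant to a sequence in template coordinates
apply_variant_bases <- function(bases, mol_pos, ref, alt) {
  have <- bases[mol_pos]
  if (!identical(have, ref)) {
    stop(sprintf(
      "variant ref allele '%s' does not match sequence base '%s' at molecule position %d",
      ref, have, mol_pos))
  }
  bases[mol_pos] <- alt
  bases
}

#' Assess the structural impact of a variant, optionally on a background
#'
#' Applies the variant to `seq`, compares the stem-pair annotations before
#' and after, and reports broken pairs (Watson-Crick/wobble lost), created
#' pairs, and any tertiary triples containing the variant position. If a
#' `background` sequence is supplied (e.g. the consensus of a species that
#' carries the variant), the variant is applied to the background too and
#' the impact is scored as *compensated* when every pair broken on `seq` is
#' held as Watson-Crick or wobble by the background's other substitutions,
#' or - for loop/tertiary variants that break no stem pair - when the
#' background substitutes a member of a touched tertiary triple.
#'
#' @param seq Gene sequence in molecule orientation (typically the human
#'   reference gene).
#' @param variant One catalogue row (list or single-row data frame with
#'   `position` or `molecule_position`, `ref`, `alt`, `gene`).
#' @param template [cloverleaf_template()].
#' @param background Optional second sequence.
#' @return List of class `mt_structure_impact`.
#' @export
assess_variant_structure <- function(seq, variant, template,
                                     background = NULL) {
  stopifnot(inherits(template, "mt_cloverleaf"))
  variant <- as.list(variant)
  mol <- variant$molecule_position
  if (is.null(mol)) mol <- molecule_position(variant$position, variant$gene)
  if (mol < 1L || mol > template$length) {
    stop("variant position outside the gene template")
  }
  bases <- template_bases(seq, template)
  before <- annotate_cloverleaf(paste(bases, collapse = ""), template)
  after_bases <- apply_variant_bases(bases, mol, variant$ref, variant$alt)
  after <- annotate_cloverleaf(paste(after_bases, collapse = ""), template)

  good <- c("watson_crick", "wobble")
  changed <- which(before$pair_class != after$pair_class)
  broken <- changed[before$pair_class[changed] %in% good &
                      !(after$pair_class[changed] %in% good)]
  created <- changed[!(before$pair_class[changed] %in% "watson_crick") &
                       after$pair_class[changed] == "watson_crick"]
  touched <- Filter(function(tr) mol %in% tr, template$tertiary)

  compensated <- FALSE
  compensating <- integer(0)
  if (!is.null(background)) {
    bg <- template_bases(background, template)
    if (!identical(bg[mol], variant$alt)) {
      bg <- apply_variant_bases(bg, mol, variant$ref, variant$alt)
    }
    bg_ann <- annotate_cloverleaf(paste(bg, collapse = ""), template)
    if (length(broken)) {
      held <- vapply(broken, function(i) {
        bg_ann$pair_class[i] %in% good
      }, TRUE)
      if (all(held)) {
        compensated <- TRUE
        compensating <- sort(setdiff(unique(unlist(lapply(broken,
          function(i) {
            ps <- c(before$pos5[i], before$pos3[i])
            ps[bg[ps] != bases[ps]]
          }))), mol))
      }
    } else if (length(touched)) {
      tp <- setdiff(unique(unlist(touched)), mol)
      diffs <- tp[bg[tp] != bases[tp]]
      if (length(diffs)) {
        compensated <- TRUE
        compensating <- sort(diffs)
      }
    }
  }
  structure(list(
    variant = variant,
    pairs_before = before,
    pairs_after = after,
    stem_pairs_broken = before[broken, , drop = FALSE],
    stem_pairs_created = after[created, , drop = FALSE],
    tertiary_triplets_touched = touched,
    compensated = compensated,
    compensating_positions = compensating
  ), class = "mt_structure_impact")
}

#' Dot-bracket rendering of a template
#'
#' `(` and `)` mark the 5' and 3' halves of the annotated stems, `.`
#' everything else; useful for eyeballing templates and exporting
#' structures.
#'
#' @param template [cloverleaf_template()].
#' @return Single string of length `template$length`.
#' @export
dot_bracket <- function(template) {
  stopifnot(inherits(template, "mt_cloverleaf"))
  out <- rep(".", template$length)
  out[template$pairs$pos5] <- "("
  out[template$pairs$pos3] <- ")"
  paste(out, collapse = "")
}
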