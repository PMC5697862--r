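#' Screen a variant catalogue across species panels
#'
#' For every species x variant cell, reads the alignment column mapped from
#' the variant's rCRS position and counts carriers of the alternate allele.
#' Rows showing `N` or an alignment gap at that column are excluded from the
#' denominator (unless the variant is itself a deletion, for which the gap
#' character *is* the alternate allele); the exclusion count is reported.
#' Status is `monomorphic` when every evaluable sequence carries the
#' alternate allele (a single-sequence species can be monomorphic),
#' `polymorphic` when some do, `absent` when none do, and `not_evaluable`
#' when no row is evaluable.
#'
#' @param panels Named list of [anchor_msa()] alignments, one per species.
#' @param catalogue Catalogue data frame from [load_catalogue()].
#' @return Data frame with one row per species x variant: `species`,
#'   `position`, `ref`, `alt`, `carriers`, `total`, `excluded`, `frequency`,
#'   `status`.
#' @export
screen_variants <- function(panels, catalogue) {
  stopifnot(length(panels) >= 1L, nrow(catalogue) >= 1L)
  if (is.null(names(panels))) stop("panels must be named by species")
  out <- list()
  for (sp in names(panels)) {
    msa <- panels[[sp]]
    rows <- do.call(rbind, strsplit(unname(msa$rows), ""))
    for (v in seq_len(nrow(catalogue))) {
      col <- rcrs_to_column(msa, catalogue$position[v])
      alleles <- rows[, col]
      alt <- catalogue$alt[v]
      if (alt == "-") {
        evaluable <- alleles != "N"
      } else {
        evaluable <- !(alleles %in% c("N", "-"))
      }
      total <- sum(evaluable)
      carriers <- sum(alleles[evaluable] == alt)
      status <- if (total == 0L) {
        "not_evaluable"
      } else if (carriers == 0L) {
        "absent"
      } else if (carriers == total) {
        "monomorphic"
      } else {
        "polymorphic"
      }
      out[[length(out) + 1L]] <- data.frame(
        species = sp, position = catalogue$position[v],
        ref = catalogue$ref[v], alt = alt,
        carriers = carriers, total = total,
        excluded = length(alleles) - total,
        frequency = if (total > 0L) carriers / total else NA_real_,
        status = status, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate screen cells over a taxonomy rank
#'
#' Sums carriers and totals over all species assigned to each taxon label
#' and reports the pooled frequency to three decimals (half-up), the
#' convention of per-order frequency tables. Species without a label at the
#' requested rank are grouped under `"unassigned"`.
#'
#' @param cells Screen table from [screen_variants()], restricted to one
#'   variant (or carrying a `position` the caller has filtered on).
#' @param taxa Named character vector mapping species to a taxon label at
#'   the chosen rank (e.g. order); or a data frame with `species` and
#'   `taxon` columns.
#' @return Data frame `taxon`, `carriers`, `total`, `frequency`, sorted by
#'   descending frequency.
#' @export
aggregate_by_taxon <- function(cells, taxa) {
  if (is.data.frame(taxa)) {
    taxa <- stats::setNames(taxa$taxon, taxa$species)
  }
  lab <- unname(taxa[cells$species])
  lab[is.na(lab) | !nzchar(lab)] <- "unassigned"
  carriers <- tapply(cells$carriers, lab, sum)
  totals <- tapply(cells$total, lab, sum)
  out <- data.frame(taxon = names(carriers),
                    carriers = as.integer(carriers),
                    total = as.integer(totals),
                    stringsAsFactors = FALSE)
  out$frequency <- round_half_up(out$carriers / out$total, 3)
  out <- out[order(-out$frequency, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Joint carriage of a target variant and candidate compensators
#'
#' Per sequence, reads the alleles at the target position and at each
#' candidate position; reports 2x2 counts and the percentage of target
#' carriers that also carry the candidate (integer, half-up - the
#' convention of the carnivore co-occurrence table). Rows not evaluable at
#' either position are excluded and counted.
#'
#' @param panel An [anchor_msa()] alignment.
#' @param target One catalogue row (the anchoring variant, e.g. 3243A>G).
#' @param candidates Catalogue rows of candidate compensators.
#' @return List with `per_sequence` (data frame of joint alleles) and
#'   `table` (one row per candidate: counts `both`, `target_only`,
#'   `candidate_only`, `neither`, `excluded`, and
#'   `pct_target_with_candidate`).
#' @export
cooccurrence <- function(panel, target, candidates) {
  stopifnot(inherits(panel, "mt_anchored"))
  target <- as.list(target)
  rows <- do.call(rbind, strsplit(unname(panel$rows), ""))
  ids <- names(panel$rows)
  t_col <- rcrs_to_column(panel, target$position)
  t_al <- rows[, t_col]
  per_seq <- data.frame(id = ids, target_allele = t_al,
                        stringsAsFactors = FALSE)
  tab <- list()
  for (v in seq_len(nrow(candidates))) {
    c_col <- rcrs_to_column(panel, candidates$position[v])
    c_al <- rows[, c_col]
    per_seq[[paste0("pos", candidates$position[v])]] <- c_al
    ok_t <- if (target$alt == "-") t_al != "N" else !(t_al %in% c("N", "-"))
    ok_c <- if (candidates$alt[v] == "-") c_al != "N" else
      !(c_al %in% c("N", "-"))
    ok <- ok_t & ok_c
    has_t <- t_al == target$alt & ok
    has_c <- c_al == candidates$alt[v] & ok
    both <- sum(has_t & has_c)
    tab[[v]] <- data.frame(
      target_position = target$position,
      candidate_position = candidates$position[v],
      both = both,
      target_only = sum(has_t & !has_c),
      candidate_only = sum(!has_t & has_c & ok),
      neither = sum(ok & !has_t & !has_c),
      excluded = sum(!ok),
      pct_target_with_candidate = if (sum(has_t) > 0L) {
        round_half_up(100 * both / sum(has_t))
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  }
  list(per_sequence = per_seq, table = do.call(rbind, tab))
}

#' Carrier percentage table in the style of a per-species report
#'
#' @param cells Screen table from [screen_variants()].
#' @return Same table with a `percent` column (integer, half-up).
#' @export
screen_percentages <- function(cells) {
  cells$percent <- round_half_up(100 * cells$frequency)
  cells
}
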