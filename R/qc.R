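#' Sequence quality-control parameters
#'
#' Three reliability checks are applied to extracted gene sequences:
#' sequences more than `length_tolerance` nt longer or shorter than the
#' reference gene are routed to review (the desk analogue of manual
#' examination) or removed outright when `auto_exclude_length_outliers` is
#' set; sequences with more than `max_n` ambiguous bases are removed; and
#' sequences whose best percent identity against any other sequence of the
#' same species falls below `similarity_floor` are flagged for review.
#'
#' @param length_tolerance Allowed length deviation in nt (default 5).
#' @param max_n Maximum tolerated `N` count (default 5).
#' @param similarity_floor Percent identity floor against the best
#'   same-species match (default 80).
#' @param auto_exclude_length_outliers If `TRUE`, length outliers are
#'   removed instead of reviewed.
#' @return List of class `mt_qc_params`.
#' @export
qc_params <- function(length_tolerance = 5L, max_n = 5L,
                      similarity_floor = 80,
                      auto_exclude_length_outliers = FALSE) {
  stopifnot(length_tolerance >= 0, max_n >= 0,
            similarity_floor >= 0, similarity_floor <= 100)
  structure(list(length_tolerance = as.integer(length_tolerance),
                 max_n = as.integer(max_n),
                 similarity_floor = similarity_floor,
                 auto_exclude_length_outliers =
                   isTRUE(auto_exclude_length_outliers)),
            class = "mt_qc_params")
}

#' Flag within-species similarity outliers
#'
#' For every record with at least one same-species companion, computes its
#' maximum percent identity to the companions (pairwise global alignments;
#' identical sequences are deduplicated first) and flags records whose best
#' match falls below the floor - the signature of mislabelled genes or
#' contaminant sequence. Single-record species cannot be assessed and are
#' left unflagged with a warning.
#'
#' @param records Gene record data frame (`species`, `sequence`).
#' @param params [qc_params()].
#' @return Logical vector (one element per row) named by accession where
#'   available.
#' @export
similarity_outliers <- function(records, params = qc_params()) {
  n <- nrow(records)
  flag <- rep(FALSE, n)
  singles <- character(0)
  for (sp in unique(records$species)) {
    idx <- which(records$species == sp)
    if (length(idx) < 2L) {
      singles <- c(singles, sp)
      next
    }
    seqs <- records$sequence[idx]
    names(seqs) <- paste0("r", seq_along(idx))
    m <- identity_matrix(seqs)
    diag(m) <- NA
    # identical duplicates share rows in identity_matrix; best match of a
    # duplicated sequence is 100 by construction
    best <- apply(m, 1L, max, na.rm = TRUE)
    flag[idx] <- best < params$similarity_floor
  }
  if (length(singles)) {
    warning("species with a single record cannot be similarity-checked: ",
            paste(singles, collapse = ", "))
  }
  if (!is.null(records$accession)) names(flag) <- records$accession
  flag
}

#' Apply the three QC checks to a set of gene records
#'
#' Dispositions: `removed` for excess Ns (and for length outliers when
#' `auto_exclude_length_outliers`), `review` for length and similarity
#' outliers, `pass` otherwise. QC is a pure function of (sequence,
#' reference, params) and therefore idempotent: rerunning it on its own
#' passed records changes nothing.
#'
#' @param records Gene record data frame.
#' @param ref Reference gene sequence (its length anchors the length check).
#' @param params [qc_params()].
#' @return List with `passed` (records with disposition `pass`), and
#'   `report` (per-record flags and disposition plus a per-species
#'   before/after `summary` attribute, mirroring a species accounting
#'   table).
#' @export
qc_filter <- function(records, ref, params = qc_params()) {
  if (!nrow(records)) {
    warning("no records supplied to QC")
    rep_df <- data.frame(accession = character(0), species = character(0),
                         gene = character(0), length_outlier = logical(0),
                         excess_n = logical(0), low_similarity = logical(0),
                         disposition = character(0), stringsAsFactors = FALSE)
    return(list(passed = records, report = rep_df))
  }
  ref_len <- nchar(ref)
  lens <- nchar(gsub("-", "", records$sequence, fixed = TRUE))
  n_count <- nchar(records$sequence) -
    nchar(gsub("N", "", records$sequence, fixed = TRUE))
  length_outlier <- abs(lens - ref_len) > params$length_tolerance
  excess_n <- n_count > params$max_n
  low_similarity <- suppressWarnings(similarity_outliers(records, params))
  disposition <- rep("pass", nrow(records))
  disposition[low_similarity] <- "review"
  disposition[length_outlier] <- if (params$auto_exclude_length_outliers) {
    "removed"
  } else {
    "review"
  }
  disposition[excess_n] <- "removed"
  report <- data.frame(
    accession = records$accession %||% paste0("seq", seq_len(nrow(records))),
    species = records$species,
    gene = records$gene,
    length_outlier = unname(length_outlier),
    excess_n = unname(excess_n),
    low_similarity = unname(low_similarity),
    disposition = disposition,
    stringsAsFactors = FALSE
  )
  before <- table(records$species)
  after <- table(records$species[disposition == "pass"])
  summary_df <- data.frame(
    species = names(before),
    n_before = as.integer(before),
    n_after = as.integer(after[names(before)]),
    stringsAsFactors = FALSE
  )
  summary_df$n_after[is.na(summary_df$n_after)] <- 0L
  attr(report, "summary") <- summary_df
  list(passed = records[disposition == "pass", , drop = FALSE],
       report = report)
}

#' Write a QC report to TSV
#'
#' @param report QC report data frame from [qc_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
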