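#' Alignment scoring parameters
#'
#' Defaults: match +1, mismatch -1, gap -2, with terminal (end) gaps free.
#' `N` is scored as a mismatch against everything and never counts as an
#' identity.
#'
#' @param match,mismatch,gap Per-column scores.
#' @param free_end_gaps Logical; if `TRUE` leading/trailing gaps cost nothing
#'   (appropriate for slightly length-variant tRNA genes).
#' @return A list of class `mt_align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap = -2,
                         free_end_gaps = TRUE) {
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 free_end_gaps = isTRUE(free_end_gaps)),
            class = "mt_align_params")
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch dynamic programming under the configured linear gap
#' scheme. Ties are broken deterministically during traceback: a matching
#' substitution is preferred over a gap in `b` (the second/member sequence),
#' then a gap in `a`, then a mismatching substitution - so equal-score
#' alignments resolve to the identity-maximizing one and repeated runs are
#' byte-identical. Gaps inside runs of one base are then slid to the 3' end
#' of the run (the mtDNA indel naming convention).
#'
#' @param a,b DNA strings over `A,C,G,T,N` (`a` is treated as the reference).
#' @param params [align_params()].
#' @return List of class `mt_alignment` with aligned strings `a`, `b`,
#'   `alignment_length`, `identities` (columns with equal non-gap, non-N
#'   residues) and `score`.
#' @export
global_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  av <- seq_chars(toupper(a))
  bv <- seq_chars(toupper(b))
  n <- length(av); m <- length(bv)
  gp <- params$gap
  # score matrix; row i = prefix of a, col j = prefix of b (1-based +1)
  F <- matrix(0, n + 1L, m + 1L)
  if (params$free_end_gaps) {
    F[, 1L] <- 0
    F[1L, ] <- 0
  } else {
    F[, 1L] <- gp * (0:n)
    F[1L, ] <- gp * (0:m)
  }
  sub <- function(x, y) {
    if (x == y && x != "N") params$match else params$mismatch
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      F[i + 1L, j + 1L] <- max(F[i, j] + sub(av[i], bv[j]),
                               F[i, j + 1L] + gp,
                               F[i + 1L, j] + gp)
    }
  }
  if (params$free_end_gaps) {
    # alignment may end with free gaps: best cell on last row/column.
    # Deterministic end point: bottom-right cell if optimal, else deepest
    # optimal cell of the last column (trailing gap in b preferred over a).
    last_col <- F[, m + 1L]
    last_row <- F[n + 1L, ]
    best <- max(c(last_col, last_row))
    if (F[n + 1L, m + 1L] == best) {
      i <- n; j <- m
    } else if (max(last_col) == best) {
      i <- max(which(last_col == best)) - 1L; j <- m
    } else {
      i <- n; j <- max(which(last_row == best)) - 1L
    }
    ra <- character(0); rb <- character(0)
    if (i < n) { ra <- av[(i + 1L):n]; rb <- rep("-", n - i) }
    if (j < m) { ra <- rep("-", m - j); rb <- bv[(j + 1L):m] }
    score <- best
  } else {
    i <- n; j <- m; ra <- character(0); rb <- character(0)
    score <- F[n + 1L, m + 1L]
  }
  # traceback
  out_a <- character(n + m); out_b <- character(n + m); k <- 0L
  while (i > 0L || j > 0L) {
    if (params$free_end_gaps && (i == 0L || j == 0L)) {
      # leading free gaps
      while (i > 0L) { k <- k + 1L; out_a[k] <- av[i]; out_b[k] <- "-"; i <- i - 1L }
      while (j > 0L) { k <- k + 1L; out_a[k] <- "-"; out_b[k] <- bv[j]; j <- j - 1L }
      break
    }
    cur <- F[i + 1L, j + 1L]
    is_match <- i > 0L && j > 0L && av[i] == bv[j] && av[i] != "N"
    if (is_match && cur == F[i, j] + params$match) {
      k <- k + 1L; out_a[k] <- av[i]; out_b[k] <- bv[j]; i <- i - 1L; j <- j - 1L
    } else if (i > 0L && cur == F[i, j + 1L] + gp) {
      k <- k + 1L; out_a[k] <- av[i]; out_b[k] <- "-"; i <- i - 1L
    } else if (j > 0L && cur == F[i + 1L, j] + gp) {
      k <- k + 1L; out_a[k] <- "-"; out_b[k] <- bv[j]; j <- j - 1L
    } else if (i > 0L && j > 0L && cur == F[i, j] + sub(av[i], bv[j])) {
      k <- k + 1L; out_a[k] <- av[i]; out_b[k] <- bv[j]; i <- i - 1L; j <- j - 1L
    } else if (i > 0L) { # boundary rows under free end gaps
      k <- k + 1L; out_a[k] <- av[i]; out_b[k] <- "-"; i <- i - 1L
    } else {
      k <- k + 1L; out_a[k] <- "-"; out_b[k] <- bv[j]; j <- j - 1L
    }
  }
  aa <- c(rev(out_a[seq_len(k)]), ra)
  bb <- c(rev(out_b[seq_len(k)]), rb)
  norm <- normalize_gaps(aa, bb)
  aa <- norm$a; bb <- norm$b
  idents <- sum(aa == bb & aa != "-" & aa != "N")
  structure(list(a = paste(aa, collapse = ""),
                 b = paste(bb, collapse = ""),
                 alignment_length = length(aa),
                 identities = idents,
                 score = score),
            class = "mt_alignment")
}

# Within runs of an identical base, slide gaps to the 3' (right) end of the
# run: a deletion inside a homopolymer is not positionally identifiable from
# the alignment alone, and mtDNA convention names it at the 3'-most base
# (so a G lost from the 3238/3239 GG run is the 3239 deletion). Score and
# identity count are invariant under these swaps.
normalize_gaps <- function(aa, bb) {
  L <- length(aa)
  repeat {
    moved <- FALSE
    for (k in seq_len(max(L - 1L, 0L))) {
      if (bb[k] == "-" && aa[k] != "-" && aa[k + 1L] != "-" &&
          bb[k + 1L] != "-" && aa[k] == aa[k + 1L]) {
        bb[k] <- bb[k + 1L]; bb[k + 1L] <- "-"; moved <- TRUE
      } else if (aa[k] == "-" && bb[k] != "-" && bb[k + 1L] != "-" &&
                 aa[k + 1L] != "-" && bb[k] == bb[k + 1L]) {
        aa[k] <- aa[k + 1L]; aa[k + 1L] <- "-"; moved <- TRUE
      }
    }
    if (!moved) break
  }
  list(a = aa, b = bb)
}

#' Percent identity of a pairwise alignment
#'
#' 100 x identities / alignment length, to two decimals; gap columns count
#' as non-identities. E.g. 20 differences over a 75-column alignment gives
#' 73.33.
#'
#' @param aln An `mt_alignment` from [global_align()].
#' @return Numeric percent.
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "mt_alignment"))
  if (aln$alignment_length == 0L) stop("zero-length alignment")
  round_half_up(100 * aln$identities / aln$alignment_length, 2)
}

#' Reference-anchored star alignment
#'
#' Each member sequence is globally aligned to the reference gene, then the
#' pairwise gap patterns are merged into shared columns (insertions relative
#' to the reference are left-aligned within their slot and padded with gaps).
#' The result carries `column_of_rcrs`, a strictly increasing map from each
#' reference (molecule) position to its alignment column, which is what the
#' variant screen reads.
#'
#' Identical member sequences are aligned once and share the merged rows, so
#' large near-monomorphic species panels stay cheap.
#'
#' @param ref Reference gene DNA string (ungapped).
#' @param seqs Character vector of member sequences; names are used as row
#'   ids (defaults to `seq1..seqN`).
#' @param gene Optional canonical gene name; with `rcrs_start` it enables
#'   [rcrs_to_column()] lookups by rCRS coordinate.
#' @param rcrs_start rCRS position of reference molecule position 1
#'   (defaults from [rcrs_gene_table()] when `gene` is known).
#' @param params [align_params()].
#' @param flag_identity_below Members whose percent identity to the reference
#'   falls below this are still aligned but listed in `$flagged`.
#' @return Object of class `mt_anchored`.
#' @export
anchor_msa <- function(ref, seqs, gene = NULL, rcrs_start = NULL,
                       params = align_params(), flag_identity_below = 50) {
  stopifnot(length(seqs) >= 1L)
  ref <- toupper(ref)
  n <- nchar(ref)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(rcrs_start) && !is.null(gene)) {
    tab <- rcrs_gene_table()
    if (gene %in% tab$gene) rcrs_start <- tab$start[tab$gene == gene]
  }
  uniq <- unique(unname(seqs))
  per <- lapply(uniq, function(s) {
    aln <- global_align(ref, s, params)
    ra <- seq_chars(aln$a); rb <- seq_chars(aln$b)
    # slot s = 0..n: insertions (gaps in ref row) before ref position s+1
    slot <- integer(length(ra))
    pos <- 0L
    for (k in seq_along(ra)) {
      if (ra[k] != "-") pos <- pos + 1L
      slot[k] <- pos # columns at a ref base get slot=pos; insertions after it
    }
    ins <- tabulate(slot[ra == "-"] + 1L, nbins = n + 1L) # slot 0..n -> 1..n+1
    list(aln = aln, ra = ra, rb = rb, slot = slot, ins = ins,
         pid = percent_identity(aln))
  })
  names(per) <- uniq
  merged_ins <- Reduce(pmax, lapply(per, `[[`, "ins"))
  # column of each reference position in the merged alignment
  col_of <- cumsum(merged_ins[seq_len(n)]) + seq_len(n)
  ncol_total <- sum(merged_ins) + n
  build_row <- function(p) {
    row <- rep("-", ncol_total)
    # walk the pairwise alignment, emitting into merged columns
    used_ins <- integer(n + 1L) # per-slot insertion counter
    for (k in seq_along(p$ra)) {
      s <- p$slot[k]
      if (p$ra[k] == "-") {
        used_ins[s + 1L] <- used_ins[s + 1L] + 1L
        base_col <- if (s == 0L) 0L else col_of[s]
        row[base_col + used_ins[s + 1L]] <- p$rb[k]
      } else {
        row[col_of[s]] <- p$rb[k]
      }
    }
    paste(row, collapse = "")
  }
  uniq_rows <- vapply(per, build_row, "")
  ref_row <- {
    row <- rep("-", ncol_total)
    row[col_of] <- seq_chars(ref)
    paste(row, collapse = "")
  }
  rows <- uniq_rows[unname(seqs)]
  names(rows) <- names(seqs)
  pids <- vapply(per, `[[`, 0, "pid")[unname(seqs)]
  flagged <- names(seqs)[pids < flag_identity_below]
  structure(list(ref = ref, ref_row = ref_row, rows = rows,
                 ncol = ncol_total, column_of_rcrs = as.integer(col_of),
                 gene = gene, rcrs_start = rcrs_start,
                 identity = unname(pids), flagged = flagged),
            class = "mt_anchored")
}

#' Map an rCRS position to its alignment column
#'
#' @param msa An `mt_anchored` alignment whose `rcrs_start` is known.
#' @param rcrs_pos rCRS genome position (1-based).
#' @return Integer column index in the anchored alignment.
#' @export
rcrs_to_column <- function(msa, rcrs_pos) {
  stopifnot(inherits(msa, "mt_anchored"))
  if (is.null(msa$rcrs_start)) {
    stop("anchored alignment has no rCRS anchor (rcrs_start unknown)")
  }
  mol <- rcrs_pos - msa$rcrs_start + 1L
  nref <- nchar(msa$ref)
  if (any(mol < 1L | mol > nref)) {
    stop(sprintf("rCRS position %s outside the reference gene interval [%d..%d]",
                 paste(rcrs_pos[mol < 1L | mol > nref], collapse = ","),
                 msa$rcrs_start, msa$rcrs_start + nref - 1L))
  }
  msa$column_of_rcrs[mol]
}

#' Pairwise percent-identity matrix
#'
#' Convenience wrapper used by QC: aligns every pair of unique sequences and
#' returns the full symmetric matrix over the input ids.
#'
#' @param seqs Named character vector of sequences.
#' @param params [align_params()].
#' @return Symmetric numeric matrix of percent identities (diagonal 100).
#' @export
identity_matrix <- function(seqs, params = align_params()) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  uniq <- unique(unname(seqs))
  k <- length(uniq)
  um <- matrix(100, k, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        pid <- percent_identity(global_align(uniq[i], uniq[j], params))
        um[i, j] <- pid; um[j, i] <- pid
      }
    }
  }
  idx <- match(unname(seqs), uniq)
  m <- um[idx, idx, drop = FALSE]
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}
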