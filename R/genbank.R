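#' Parse a GenBank flat file of mitochondrial genomes
#'
#' A minimal reader for the subset of the GenBank flat-file grammar that
#' annotated mitochondrial genome records use: LOCUS/ACCESSION headers, the
#' ORGANISM line with its indented taxonomy continuation, a FEATURES table
#' with `a..b`, `complement(...)` and `join(...)` locations plus
#' `/qualifier="value"` lines, and the ORIGIN sequence block. Multi-record
#' files (records terminated by `//`) are supported.
#'
#' @param x Path to a GenBank file, or the file's text (single string or
#'   character vector of lines).
#' @return List of genome records; each is a list with `accession`,
#'   `organism`, `lineage` (character vector), `sequence` (uppercase DNA)
#'   and `features` (data frame with `kind`, `product`, `strand`, `start`,
#'   `end` and a list-column `intervals` of start/end matrices).
#' @export
parse_genbank <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    lines <- strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- x
  }
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) stop("no GenBank record terminator '//' found")
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- Map(function(s, e) lines[s:e], starts, ends)
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  lapply(recs, parse_genbank_record)
}

parse_genbank_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  name <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                      "\\s+")[[1]][1] else "<unnamed>"
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else name
  org_i <- grep("^\\s{2}ORGANISM", lines)
  organism <- NA_character_; lineage <- character(0)
  if (length(org_i)) {
    organism <- trimws(sub("^\\s{2}ORGANISM", "", lines[org_i[1]]))
    j <- org_i[1] + 1L
    lin <- character(0)
    while (j <= length(lines) && grepl("^\\s{10,}\\S", lines[j])) {
      lin <- c(lin, trimws(lines[j])); j <- j + 1L
    }
    if (length(lin)) {
      lineage <- trimws(strsplit(sub("\\.\\s*$", "", paste(lin, collapse = " ")),
                                 ";")[[1]])
    }
  }
  feat_i <- grep("^FEATURES", lines)
  if (!length(feat_i)) {
    stop("GenBank record ", accession, ": missing FEATURES table")
  }
  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) {
    stop("GenBank record ", accession, ": missing ORIGIN sequence")
  }
  seq_lines <- lines[(origin_i[1] + 1L):(length(lines) - 1L)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  flines <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
  key_idx <- grep("^\\s{5}\\S", flines)
  feats <- list()
  for (k in seq_along(key_idx)) {
    from <- key_idx[k]
    to <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(flines)
    block <- flines[from:to]
    head_parts <- strsplit(trimws(block[1]), "\\s+")[[1]]
    kind <- head_parts[1]
    loc <- paste(head_parts[-1], collapse = "")
    # location may continue on following lines until the first qualifier
    q_start <- grep("^\\s+/", block)
    extra <- if (length(q_start)) {
      if (q_start[1] > 2L) block[2:(q_start[1] - 1L)] else character(0)
    } else if (length(block) > 1L) block[-1] else character(0)
    loc <- paste0(loc, paste(trimws(extra), collapse = ""))
    quals <- grep("^\\s+/", block, value = TRUE)
    product <- NA_character_
    pq <- grep("/product=", quals, value = TRUE)
    if (length(pq)) {
      product <- sub("^\\s*/product=", "", trimws(pq[1]))
      product <- gsub("^\"|\"$", "", product)
    }
    parsed <- parse_location(loc)
    feats[[length(feats) + 1L]] <- list(kind = kind, product = product,
                                        strand = parsed$strand,
                                        intervals = parsed$intervals)
  }
  feat_df <- data.frame(
    kind = vapply(feats, `[[`, "", "kind"),
    product = vapply(feats, `[[`, "", "product"),
    strand = vapply(feats, `[[`, "", "strand"),
    start = vapply(feats, function(f) min(f$intervals[, 1L]), 0),
    end = vapply(feats, function(f) max(f$intervals[, 2L]), 0),
    stringsAsFactors = FALSE
  )
  feat_df$intervals <- lapply(feats, `[[`, "intervals")
  bad <- feat_df$end > nchar(sequence) | feat_df$start < 1
  if (any(bad)) {
    stop("GenBank record ", accession, ": feature interval outside sequence")
  }
  list(accession = accession, organism = organism, lineage = lineage,
       sequence = sequence, features = feat_df)
}

# "a..b", "complement(a..b)", "join(a..b,c..d)", "complement(join(...))"
parse_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  spans <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- t(vapply(spans, function(s) {
    m <- regmatches(s, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", trimws(s)))[[1]]
    if (length(m) != 3L) stop("cannot parse feature location: ", s)
    as.integer(m[2:3])
  }, integer(2)))
  dimnames(iv) <- NULL
  list(strand = strand, intervals = iv)
}

#' Extract annotated tRNA genes from a genome record
#'
#' Emits one gene record per `tRNA` feature: interval pieces are
#' concatenated in annotation order and minus-strand features are
#' reverse-complemented, so every sequence is in the molecule's coding
#' sense. Product labels are normalized with [normalize_product()];
#' features lacking a recognizable product are kept but flagged for review
#' (with a warning) rather than guessed.
#'
#' @param record One record from [parse_genbank()].
#' @return Data frame with `accession`, `species`, `lineage`, `gene`,
#'   `sequence`, `start`, `end`, `strand`, `review_reason` (`NA` for clean
#'   rows).
#' @export
extract_trna_genes <- function(record) {
  fe <- record$features
  trna <- fe[fe$kind == "tRNA", , drop = FALSE]
  if (!nrow(trna)) {
    warning("record ", record$accession, ": no tRNA features annotated")
    return(empty_gene_df())
  }
  rows <- lapply(seq_len(nrow(trna)), function(i) {
    iv <- trna$intervals[[i]]
    pieces <- apply(iv, 1L, function(ab) {
      substr(record$sequence, ab[1], ab[2])
    })
    s <- paste(pieces, collapse = "")
    if (trna$strand[i] == "-") s <- revcomp(s)
    gene <- normalize_product(trna$product[i])
    reason <- NA_character_
    if (is.na(trna$product[i]) || !nzchar(trna$product[i])) {
      reason <- "missing product label"
    } else if (is.na(gene)) {
      reason <- paste0("unrecognized product label '", trna$product[i], "'")
    }
    data.frame(accession = record$accession, species = record$organism,
               lineage = paste(record$lineage, collapse = "; "),
               gene = gene, sequence = s,
               start = trna$start[i], end = trna$end[i],
               strand = trna$strand[i], review_reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(!is.na(out$review_reason))) {
    warning("record ", record$accession, ": ",
            sum(!is.na(out$review_reason)),
            " tRNA feature(s) routed to review (product label)")
  }
  rownames(out) <- NULL
  out
}

empty_gene_df <- function() {
  data.frame(accession = character(0), species = character(0),
             lineage = character(0), gene = character(0),
             sequence = character(0), start = integer(0), end = integer(0),
             strand = character(0), review_reason = character(0),
             stringsAsFactors = FALSE)
}

#' Assign Leu/Ser gene records to the correct paralog
#'
#' mtDNA has two tRNA-Leu and two tRNA-Ser genes; records whose product
#' label is generic ("tRNA-Leu") - or carries a specific but possibly wrong
#' paralog label - are scored by percent identity against both paralog
#' references and assigned to the better one. Exact score ties are not
#' guessed: the record keeps its label and is flagged for review
#' (`paralog_review`), mirroring a manual-inspection bucket. Non-paralog
#' genes pass through unchanged.
#'
#' @param records Gene record data frame from [extract_trna_genes()].
#' @param refs Named vector of paralog reference sequences
#'   ([paralog_references()]).
#' @param params [align_params()].
#' @return `records` with `gene` reassigned where warranted and logical
#'   columns `paralog_assigned` and `paralog_review` added.
#' @export
disambiguate_paralogs <- function(records, refs = paralog_references(),
                                  params = align_params()) {
  families <- list(
    "tRNA-Leu" = c("tRNA-Leu(UUR)", "tRNA-Leu(CUN)"),
    "tRNA-Ser" = c("tRNA-Ser(UCN)", "tRNA-Ser(AGY)")
  )
  all_paralogs <- unlist(families)
  if (!all(all_paralogs %in% names(refs))) {
    stop("refs must contain both Leu and both Ser paralog references")
  }
  records$paralog_assigned <- FALSE
  records$paralog_review <- FALSE
  target <- which(records$gene %in% c(names(families), all_paralogs))
  if (!length(target)) return(records)
  # score each unique candidate sequence once
  cache <- new.env(parent = emptyenv())
  score <- function(s, ref_gene) {
    key <- paste(ref_gene, s)
    if (is.null(cache[[key]])) {
      cache[[key]] <- percent_identity(global_align(refs[[ref_gene]], s,
                                                    params))
    }
    cache[[key]]
  }
  for (i in target) {
    fam <- if (grepl("Leu", records$gene[i], fixed = TRUE)) {
      families[["tRNA-Leu"]]
    } else {
      families[["tRNA-Ser"]]
    }
    pids <- vapply(fam, function(g) score(records$sequence[i], g), 0)
    if (pids[1] == pids[2]) {
      records$paralog_review[i] <- TRUE
    } else {
      best <- fam[which.max(pids)]
      records$paralog_assigned[i] <- best != records$gene[i]
      records$gene[i] <- best
    }
  }
  records
}
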