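#' Collapse aligned sequences into haplotypes over selected positions
#'
#' Reads the alleles at the alignment columns mapped from the given rCRS
#' positions and groups identical character vectors. The deletion character
#' `-` is a regular fifth state. Counts sum to the panel size.
#'
#' @param panel An [anchor_msa()] alignment.
#' @param positions Integer rCRS positions to use as characters.
#' @return Object of class `mt_haplotypes`: list with `positions`, `alleles`
#'   (character matrix, one row per haplotype), `count`, `label`,
#'   `observed`.
#' @export
collapse_haplotypes <- function(panel, positions) {
  stopifnot(inherits(panel, "mt_anchored"), length(positions) >= 1L)
  cols <- vapply(positions, function(p) rcrs_to_column(panel, p), 1L)
  rows <- do.call(rbind, strsplit(unname(panel$rows), ""))
  mat <- rows[, cols, drop = FALSE]
  key <- apply(mat, 1L, paste, collapse = "")
  tab <- table(key)
  # deterministic order: descending count, then lexicographic
  ord <- order(-as.integer(tab), names(tab))
  keys <- names(tab)[ord]
  alleles <- do.call(rbind, strsplit(keys, ""))
  colnames(alleles) <- as.character(positions)
  structure(list(positions = as.integer(positions),
                 alleles = alleles,
                 count = as.integer(tab)[ord],
                 label = paste0("H", seq_along(keys)),
                 observed = rep(TRUE, length(keys))),
            class = "mt_haplotypes")
}

#' Build haplotypes from a character table
#'
#' Accepts a data frame in the layout of a printed haplotype table: a label
#' column, one column per position (numeric names), and a count column.
#'
#' @param df Data frame.
#' @param label_col,count_col Column names (defaults `label`, `count`).
#' @return `mt_haplotypes` object.
#' @export
haplotypes_from_table <- function(df, label_col = "label",
                                  count_col = "count") {
  pos_cols <- setdiff(names(df), c(label_col, count_col))
  positions <- as.integer(gsub("^X", "", pos_cols))
  if (any(is.na(positions))) stop("position columns must be numeric names")
  alleles <- as.matrix(df[, pos_cols, drop = FALSE])
  colnames(alleles) <- as.character(positions)
  rownames(alleles) <- NULL
  structure(list(positions = positions, alleles = alleles,
                 count = as.integer(df[[count_col]]),
                 label = as.character(df[[label_col]]),
                 observed = rep(TRUE, nrow(df))),
            class = "mt_haplotypes")
}

hamming <- function(a, b) sum(a != b)

dist_matrix <- function(alleles) {
  n <- nrow(alleles)
  d <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- hamming(alleles[i, ], alleles[j, ])
      }
    }
  }
  d
}

# Minimum spanning network over rows of an allele matrix: process distance
# levels in ascending order; at each level (relaxed by epsilon) connect all
# pairs lying in components that were distinct before the level started.
msn_edges <- function(alleles, epsilon = 0L) {
  n <- nrow(alleles)
  if (n == 1L) {
    return(data.frame(from = integer(0), to = integer(0),
                      weight = integer(0)))
  }
  d <- dist_matrix(alleles)
  comp <- seq_len(n)
  edges <- list()
  levels <- sort(unique(d[upper.tri(d)]))
  for (lev in levels) {
    if (length(unique(comp)) == 1L) break
    comp_before <- comp
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (d[i, j] <= lev + epsilon && d[i, j] >= lev &&
            comp_before[i] != comp_before[j]) {
          edges[[length(edges) + 1L]] <- c(i, j, d[i, j])
          if (comp[i] != comp[j]) {
            comp[comp == comp[j]] <- comp[i]
          }
        }
      }
    }
  }
  m <- do.call(rbind, edges)
  if (is.null(m)) m <- matrix(integer(0), 0, 3)
  data.frame(from = m[, 1], to = m[, 2], weight = m[, 3])
}

# majority-rule median of three character vectors; on a three-way tie the
# first vector's state is kept (deterministic, documented).
median_vector <- function(u, v, w) {
  vapply(seq_along(u), function(k) {
    s <- c(u[k], v[k], w[k])
    t <- table(s)
    if (max(t) >= 2L) names(t)[which.max(t)] else u[k]
  }, "")
}

#' Median-joining haplotype network
#'
#' Builds the minimum spanning network over the observed haplotypes at
#' tolerance `epsilon`, then repeatedly augments it with majority-rule
#' median (consensus) vectors of linked triples - the inferred unsampled or
#' ancestral haplotypes - rebuilding the network until no new median arises.
#' Superfluous medians (unobserved nodes of degree < 3) are pruned. All
#' characters are weighted equally; the deletion state participates like
#' any base. Node order and tie handling are deterministic, so outputs are
#' byte-stable.
#'
#' @param haps `mt_haplotypes` from [collapse_haplotypes()].
#' @param epsilon Non-negative integer tolerance (default 0; the network
#'   then contains the minimum spanning network).
#' @param max_iter Safety cap on augmentation rounds.
#' @return Object of class `mt_haplonet`: `nodes` (data frame `label`,
#'   `observed`, `count`), `alleles` matrix, `edges` (data frame `from`,
#'   `to`, `weight`, `positions` list-column of mutated rCRS positions,
#'   `changes` list-column of `pos:a>b` strings).
#' @export
median_joining <- function(haps, epsilon = 0L, max_iter = 10L) {
  stopifnot(inherits(haps, "mt_haplotypes"))
  alleles <- haps$alleles
  observed <- rep(TRUE, nrow(alleles))
  counts <- haps$count
  labels <- haps$label
  for (iter in seq_len(max_iter)) {
    ed <- msn_edges(alleles, epsilon)
    if (!nrow(ed)) break
    adj <- lapply(seq_len(nrow(alleles)), function(i) {
      sort(unique(c(ed$to[ed$from == i], ed$from[ed$to == i])))
    })
    new_medians <- list()
    n <- nrow(alleles)
    for (u in seq_len(n)) {
      nb <- adj[[u]]
      if (length(nb) < 2L) next
      pairs <- utils::combn(nb, 2L)
      for (p in seq_len(ncol(pairs))) {
        v <- pairs[1L, p]; w <- pairs[2L, p]
        m <- median_vector(alleles[u, ], alleles[v, ], alleles[w, ])
        key <- paste(m, collapse = "")
        existing <- apply(alleles, 1L, paste, collapse = "")
        if (!(key %in% existing) &&
            !(key %in% names(new_medians))) {
          new_medians[[key]] <- m
        }
      }
    }
    if (!length(new_medians)) break
    add <- do.call(rbind, new_medians[sort(names(new_medians))])
    alleles <- rbind(alleles, add)
    observed <- c(observed, rep(FALSE, nrow(add)))
    counts <- c(counts, rep(0L, nrow(add)))
    labels <- c(labels, paste0("mv", seq_len(nrow(add)) +
                                 sum(!observed) - nrow(add)))
  }
  # prune unobserved nodes of degree < 3
  repeat {
    ed <- msn_edges(alleles, epsilon)
    deg <- tabulate(c(ed$from, ed$to), nbins = nrow(alleles))
    drop <- which(!observed & deg < 3L)
    if (!length(drop)) break
    keep <- setdiff(seq_len(nrow(alleles)), drop)
    alleles <- alleles[keep, , drop = FALSE]
    observed <- observed[keep]
    counts <- counts[keep]
    labels <- labels[keep]
  }
  ed <- msn_edges(alleles, epsilon)
  # guarantee the observed-haplotype minimum spanning network is contained:
  # a median chain can otherwise displace a direct alternative link and
  # hide a reticulation
  obs_idx <- which(observed)
  obs_msn <- msn_edges(alleles[obs_idx, , drop = FALSE], epsilon)
  if (nrow(obs_msn)) {
    add <- data.frame(from = obs_idx[obs_msn$from],
                      to = obs_idx[obs_msn$to],
                      weight = obs_msn$weight)
    ekey <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    akey <- paste(pmin(add$from, add$to), pmax(add$from, add$to))
    ed <- rbind(ed, add[!(akey %in% ekey), , drop = FALSE])
  }
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  ed$positions <- lapply(seq_len(nrow(ed)), function(k) {
    haps$positions[alleles[ed$from[k], ] != alleles[ed$to[k], ]]
  })
  ed$changes <- lapply(seq_len(nrow(ed)), function(k) {
    diff <- which(alleles[ed$from[k], ] != alleles[ed$to[k], ])
    vapply(diff, function(c0) {
      pair <- sort(c(alleles[ed$from[k], c0], alleles[ed$to[k], c0]))
      paste0(haps$positions[c0], ":", pair[1], ">", pair[2])
    }, "")
  })
  structure(list(
    nodes = data.frame(label = labels, observed = observed,
                       count = counts,
                       # highest-frequency haplotypes are the most plausible
                       # ancestral state under the frequency heuristic
                       ancestral_candidate = observed &
                         counts == max(counts),
                       stringsAsFactors = FALSE),
    alleles = alleles,
    positions = haps$positions,
    edges = ed
  ), class = "mt_haplonet")
}

# all spanning trees of the network's edge set with minimal total weight;
# brute force over edge subsets (intended for the small haplotype networks
# this package builds). Returns a list of integer edge-index vectors.
minimum_spanning_trees <- function(net, cap = 200000L) {
  ed <- net$edges
  n <- nrow(net$alleles)
  if (n == 1L) return(list(integer(0)))
  k <- n - 1L
  if (choose(nrow(ed), k) > cap) {
    stop("network too large for exhaustive spanning-tree enumeration")
  }
  combos <- utils::combn(nrow(ed), k, simplify = FALSE)
  connected <- function(idx) {
    comp <- seq_len(n)
    for (e in idx) {
      a <- comp[ed$from[e]]; b <- comp[ed$to[e]]
      if (a != b) comp[comp == b] <- a
    }
    length(unique(comp)) == 1L
  }
  trees <- Filter(connected, combos)
  w <- vapply(trees, function(idx) sum(ed$weight[idx]), 0)
  trees[w == min(w)]
}

#' Recurrent mutations in a haplotype network
#'
#' A mutation (position plus unordered allele pair) is recurrent when it
#' labels two or more edges of some minimum-weight spanning tree of the
#' network - the tree reading of a reticulation. Alternative placements of
#' the same single event (ties in the spanning network) are not counted,
#' and different derived states at one position are different mutations.
#'
#' @param net `mt_haplonet` from [median_joining()].
#' @return Sorted integer vector of rCRS positions with a recurrent
#'   mutation (possibly empty).
#' @export
detect_recurrence <- function(net) {
  stopifnot(inherits(net, "mt_haplonet"))
  if (!nrow(net$edges)) return(integer(0))
  trees <- minimum_spanning_trees(net)
  rec <- integer(0)
  for (idx in trees) {
    muts <- unlist(net$edges$changes[idx])
    dup <- unique(muts[duplicated(muts)])
    if (length(dup)) {
      rec <- c(rec, as.integer(sub(":.*$", "", dup)))
    }
  }
  sort(unique(rec))
}

#' Export a haplotype network
#'
#' @param net `mt_haplonet`.
#' @param path Output path.
#' @param format `"tsv"` for an edge list or `"graphml"` for GraphML XML.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  nd <- net$nodes
  ed <- net$edges
  if (format == "tsv") {
    df <- data.frame(
      from = nd$label[ed$from], to = nd$label[ed$to],
      weight = ed$weight,
      positions = vapply(ed$positions, paste, "", collapse = ","),
      changes = vapply(ed$changes, paste, "", collapse = ","),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <graph edgedefault=\"undirected\">",
      sprintf("    <node id=\"%s\"><data key=\"count\">%d</data></node>",
              nd$label, nd$count),
      sprintf(
        "    <edge source=\"%s\" target=\"%s\"><data key=\"positions\">%s</data></edge>",
        nd$label[ed$from], nd$label[ed$to],
        vapply(ed$positions, paste, "", collapse = ",")),
      "  </graph>",
      "</graphml>"
    )
    writeLines(lines, path)
  }
  invisible(path)
}
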