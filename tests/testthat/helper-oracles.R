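# Independent oracles used across the suite. These deliberately avoid the
# package's own dynamic-programming / network code paths.

# Exhaustive-path alignment score oracle: enumerates every global alignment
# of a and b as a move path and scores it column by column. Leading and
# trailing runs of a single gap type are free when free_end is TRUE,
# matching the semiglobal convention used for tRNA genes.
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap = -2, free_end = TRUE) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  score_cols <- function(cols) {
    L <- length(cols)
    gap_type <- vapply(cols, function(cc) {
      if (cc[1] == "-") "a" else if (cc[2] == "-") "b" else "s"
    }, "")
    free <- rep(FALSE, L)
    if (free_end) {
      k <- 1L
      while (k <= L && gap_type[k] != "s" && gap_type[k] == gap_type[1]) {
        free[k] <- TRUE; k <- k + 1L
      }
      k <- L
      while (k >= 1L && gap_type[k] != "s" && gap_type[k] == gap_type[L]) {
        free[k] <- TRUE; k <- k - 1L
      }
    }
    s <- 0
    for (k in seq_len(L)) {
      cc <- cols[[k]]
      if (gap_type[k] != "s") {
        if (!free[k]) s <- s + gap
      } else if (cc[1] == cc[2] && cc[1] != "N") {
        s <- s + match
      } else {
        s <- s + mismatch
      }
    }
    s
  }
  rec <- function(i, j, cols) {
    if (i == n && j == m) {
      best <<- max(best, score_cols(cols))
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, c(cols, list(c(av[i + 1L], bv[j + 1L]))))
    if (i < n) rec(i + 1L, j, c(cols, list(c(av[i + 1L], "-"))))
    if (j < m) rec(i, j + 1L, c(cols, list(c("-", bv[j + 1L]))))
  }
  rec(0L, 0L, list())
  best
}

# Minimum-spanning-network oracle: edge (u,v) belongs to the MSN iff u and v
# are not connected using only strictly shorter edges.
brute_force_msn <- function(alleles) {
  n <- nrow(alleles)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(alleles[i, ] != alleles[j, ])
  }
  connected_below <- function(u, v, w) {
    seen <- u
    frontier <- u
    while (length(frontier)) {
      nxt <- integer(0)
      for (x in frontier) {
        nb <- which(d[x, ] < w & seq_len(n) != x)
        nxt <- c(nxt, setdiff(nb, seen))
      }
      nxt <- unique(nxt)
      if (v %in% nxt) return(TRUE)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    FALSE
  }
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!connected_below(i, j, d[i, j])) {
      out[[length(out) + 1L]] <- c(i, j, d[i, j])
    }
  }
  do.call(rbind, out)
}

# shortest path weight between two nodes of an mt_haplonet (Dijkstra over
# the network's edge weights), used to verify MSN links survive median
# insertion as exact-length paths
net_path_weight <- function(net, i, j) {
  n <- nrow(net$alleles)
  dist <- rep(Inf, n); dist[i] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!length(u) || is.na(u) || is.infinite(dist[u])) break
    done[u] <- TRUE
    if (u == j) break
    ed <- net$edges
    for (k in seq_len(nrow(ed))) {
      v <- if (ed$from[k] == u) ed$to[k] else if (ed$to[k] == u) ed$from[k] else next
      if (dist[u] + ed$weight[k] < dist[v]) dist[v] <- dist[u] + ed$weight[k]
    }
  }
  dist[j]
}

# one-species panel config built in code
toy_species <- function(name = "Testus species", n = 10, background = NULL,
                        injections = NULL, haplotypes = NULL,
                        lineage = c("Eukaryota", "Metazoa", "Chordata",
                                    "Mammalia", "Testorder", "Testidae")) {
  sp <- list(name = name, lineage = as.list(lineage), n_records = n)
  if (!is.null(background)) sp$background <- as.list(background)
  if (!is.null(injections)) sp$injections <- injections
  if (!is.null(haplotypes)) sp$haplotypes <- haplotypes
  sp
}

toy_config <- function(..., defects = list(), noise_rate = 0, seed = 42) {
  list(species = list(...), defects = defects, noise_rate = noise_rate,
       seed = seed)
}

# extract + disambiguate all tRNA genes from simulated GenBank text
extract_panel_genes <- function(sim) {
  recs <- parse_genbank(sim$genbank)
  genes <- do.call(rbind, lapply(recs, extract_trna_genes))
  disambiguate_paralogs(genes)
}

table4_haplotypes <- function() {
  df <- utils::read.table(
    system.file("extdata", "table4_dog_haplotypes.tsv",
                package = "mttrnascreen", mustWork = TRUE),
    sep = "\t", header = TRUE, check.names = FALSE, comment.char = "")
  haplotypes_from_table(df, count_col = "count")
}
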