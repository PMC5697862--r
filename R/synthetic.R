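# Fixed synthetic companion genes for the mini-genomes (labelled synthetic:
# realistic length/composition, not real rCRS genes).
synthetic_gene_set <- function() {
  c(
    "tRNA-Phe" = "GTTTATGTAGCTTAACTCAAAGCAAGGCACTGAAAATGCCTAGATGAGTCTCACGACTCCA",
    "tRNA-Gln" = "TAGGATGGGGTGTGATAGGTGGCACGGAGAATTTTGGATTCTCAGGGATGGGTTCGATTCTCAT"
  )
}

# deterministic spacer between genes
.spacer <- function() "CACCCTATTAACCACTCACGGGAGCTCTCCATGCATTTGGTA"

#' Load a synthetic panel configuration from YAML
#'
#' @param path YAML config (see the packaged presets
#'   `dog_panel.yaml` and `multi_order_panel.yaml` under `extdata`).
#' @return Config list of class `mt_panel_config`.
#' @export
load_panel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_panel_config(cfg)
}

#' Path to a packaged panel preset
#'
#' `"dog"` is the 391-record dog panel whose haplotype groups reproduce the
#' printed dog haplotype table; `"multi_order"` is a 10-species,
#' multi-order panel exercising monomorphic, polymorphic and compensated
#' variants.
#'
#' @param name `"dog"` or `"multi_order"`.
#' @return File path.
#' @export
panel_preset_path <- function(name = c("dog", "multi_order")) {
  name <- match.arg(name)
  fn <- c(dog = "dog_panel.yaml", multi_order = "multi_order_panel.yaml")[[name]]
  system.file("extdata", fn, package = "mttrnascreen", mustWork = TRUE)
}

as_panel_config <- function(cfg) {
  stopifnot(!is.null(cfg$species), length(cfg$species) >= 1L)
  # "n" is YAML-hostile (parsed as a boolean key); the canonical key is
  # n_records, but accept n from configs built in R
  for (i in seq_along(cfg$species)) {
    sp <- cfg$species[[i]]
    if (is.null(sp$n_records) && !is.null(sp[["n"]])) {
      sp$n_records <- sp[["n"]]
      cfg$species[[i]] <- sp
    }
    stopifnot(!is.null(sp$name), !is.null(sp$n_records), sp$n_records >= 1L)
  }
  cfg$defects <- utils::modifyList(
    list(excess_n = 0, length_outlier = 0, paralog_mislabel = 0),
    cfg$defects %||% list())
  stopifnot(all(unlist(cfg$defects) >= 0), all(unlist(cfg$defects) <= 1))
  cfg$noise_rate <- cfg$noise_rate %||% 0
  cfg$bernoulli <- isTRUE(cfg$bernoulli)
  cfg$seed <- cfg$seed %||% 1L
  class(cfg) <- "mt_panel_config"
  cfg
}

# apply named substitutions (rCRS position -> allele, "-" deletes) to the
# Leu(UUR) gene sequence kept as a character vector in molecule coordinates
apply_subs <- function(bases, subs) {
  if (!length(subs)) return(bases)
  pos <- as.integer(names(subs))
  mol <- pos - 3230L + 1L
  stopifnot(all(mol >= 1L & mol <= length(bases)))
  bases[mol] <- unlist(subs)
  bases
}

#' Simulate a multi-species GenBank panel with known truth
#'
#' Emits one annotated mini-genome GenBank record per sequence: six tRNA
#' features (including both Leu/Ser paralog pairs, one light-strand gene)
#' around a species-specific tRNA-Leu(UUR) gene built from the rCRS gene
#' plus per-species background substitutions and injected variants.
#' Injection is deterministic: a variant configured with `count` k (or
#' `frequency` f, k = ceiling(f n)) is planted in exactly k records chosen
#' by the seeded generator, unless `bernoulli: true` requests stochastic
#' planting. Species may instead define whole `haplotypes` groups (allele
#' vectors with counts), which is how the dog preset encodes its six
#' haplogroups. Configured defect rates plant excess-N, truncation and
#' paralog-mislabel defects, all recorded in the truth table.
#'
#' @param config [load_panel_config()] list (or a list accepted by it).
#' @param seed Integer seed; overrides `config$seed`.
#' @return List with `genbank` (flat-file text, single string) and `truth`
#'   (list of data frames: `records` with per-record defect labels,
#'   `genes` with every emitted gene interval/strand/sequence, `alleles`
#'   with the planted allele at every configured position).
#' @export
simulate_panel <- function(config, seed = NULL) {
  if (!inherits(config, "mt_panel_config")) config <- as_panel_config(config)
  seed <- seed %||% config$seed
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  leu <- seq_chars(rcrs_leu_uur())
  recs <- list()
  acc_i <- 0L
  for (sp in config$species) {
    n <- as.integer(sp$n_records)
    base <- apply_subs(leu, sp$background %||% list())
    # per-record allele plan at configured positions
    plan_pos <- character(0)
    plan <- NULL
    if (!is.null(sp$haplotypes)) {
      hp <- sp$haplotypes
      counts <- vapply(hp$groups, function(g) as.integer(g$count), 1L)
      if (sum(counts) != n) {
        stop("species ", sp$name, ": haplotype group counts must sum to n")
      }
      plan_pos <- as.character(hp$positions)
      plan <- do.call(rbind, lapply(seq_along(hp$groups), function(g) {
        matrix(rep(unlist(hp$groups[[g]]$alleles), counts[g]),
               ncol = length(hp$positions), byrow = TRUE)
      }))
      # deterministic shuffle of group membership across record indices
      ord <- sample.int(n)
      plan <- plan[ord, , drop = FALSE]
    } else if (!is.null(sp$injections)) {
      inj <- sp$injections
      plan_pos <- vapply(inj, function(x) as.character(x$position), "")
      if (anyDuplicated(plan_pos)) {
        stop("species ", sp$name,
             ": contradictory injections at one position")
      }
      plan <- matrix(rep(base[as.integer(plan_pos) - 3230L + 1L], each = n),
                     nrow = n)
      carrier_sets <- list()
      for (k in seq_along(inj)) {
        v <- inj[[k]]
        kn <- if (!is.null(v$count)) {
          as.integer(v$count)
        } else if (config$bernoulli) {
          sum(stats::runif(n) < v$frequency)
        } else {
          as.integer(ceiling(v$frequency * n))
        }
        if (kn > n) stop("injection count exceeds n for ", sp$name)
        carriers <- if (!is.null(v$link) &&
                        !is.null(carrier_sets[[as.character(v$link)]])) {
          linked <- carrier_sets[[as.character(v$link)]]
          if (kn >= length(linked)) {
            # carry everything the linked variant carries, plus extras
            extra <- setdiff(sample.int(n), linked)
            c(linked, extra[seq_len(kn - length(linked))])
          } else {
            linked[seq_len(kn)]
          }
        } else {
          sample.int(n, kn)
        }
        carrier_sets[[plan_pos[k]]] <- carriers
        plan[carriers, k] <- v$alt
      }
    }
    for (r in seq_len(n)) {
      acc_i <- acc_i + 1L
      bases <- base
      if (!is.null(plan)) {
        bases[as.integer(plan_pos) - 3230L + 1L] <- plan[r, ]
      }
      if (config$noise_rate > 0 && stats::runif(1) < config$noise_rate) {
        # background noise at a non-configured position
        free <- setdiff(seq_along(bases),
                        as.integer(plan_pos) - 3230L + 1L)
        p <- sample(free, 1L)
        bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
      }
      leu_seq <- paste(bases[bases != "-"], collapse = "")
      pr <- paralog_references()
      gs <- synthetic_gene_set()
      genes <- data.frame(
        gene = c("tRNA-Phe", "tRNA-Leu(UUR)", "tRNA-Gln", "tRNA-Ser(UCN)",
                 "tRNA-Ser(AGY)", "tRNA-Leu(CUN)"),
        product = c("tRNA-Phe", "tRNA-Leu(UUR)", "tRNA-Gln", "tRNA-Ser(UCN)",
                    "tRNA-Ser(AGY)", "tRNA-Leu(CUN)"),
        sequence = c(gs[["tRNA-Phe"]], leu_seq, gs[["tRNA-Gln"]],
                     pr[["tRNA-Ser(UCN)"]], pr[["tRNA-Ser(AGY)"]],
                     pr[["tRNA-Leu(CUN)"]]),
        strand = c("+", "+", "-", "-", "+", "+"),
        stringsAsFactors = FALSE
      )
      alleles <- if (length(plan_pos)) {
        stats::setNames(as.list(plan[r, ]), plan_pos)
      } else {
        list()
      }
      recs[[acc_i]] <- list(
        accession = sprintf("SYN%05d", acc_i),
        species = sp$name,
        lineage = unlist(sp$lineage %||% list("Eukaryota", "Metazoa",
                                              "Chordata")),
        genes = genes,
        alleles = alleles,
        defects = character(0)
      )
    }
  }
  recs <- degrade(recs, config$defects)
  assemble_panel(recs)
}

#' Plant QC defects into simulated records
#'
#' For each defect type, `round(rate * n)` records are chosen by the seeded
#' generator: `excess_n` replaces six Leu(UUR) bases with `N`,
#' `length_outlier` truncates the gene by six nt, and `paralog_mislabel`
#' swaps the Leu(UUR) product label to the other Leu paralog. Every planted
#' defect is recorded on the record and surfaces in the truth table.
#'
#' @param recs Internal record list from [simulate_panel()].
#' @param defect_config List of rates in `[0,1]`:
#'   `excess_n`, `length_outlier`, `paralog_mislabel`.
#' @return The record list with defects applied.
#' @export
degrade <- function(recs, defect_config) {
  rates <- utils::modifyList(
    list(excess_n = 0, length_outlier = 0, paralog_mislabel = 0),
    defect_config %||% list())
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1))
  n <- length(recs)
  pick <- function(rate) {
    k <- round(rate * n)
    if (k == 0L) integer(0) else sample.int(n, k)
  }
  for (i in pick(rates$excess_n)) {
    g <- which(recs[[i]]$genes$gene == "tRNA-Leu(UUR)")
    s <- seq_chars(recs[[i]]$genes$sequence[g])
    at <- sample(seq_along(s), 6L)
    s[at] <- "N"
    recs[[i]]$genes$sequence[g] <- paste(s, collapse = "")
    recs[[i]]$defects <- c(recs[[i]]$defects, "excess_n")
  }
  for (i in pick(rates$length_outlier)) {
    g <- which(recs[[i]]$genes$gene == "tRNA-Leu(UUR)")
    s <- recs[[i]]$genes$sequence[g]
    recs[[i]]$genes$sequence[g] <- substr(s, 1L, nchar(s) - 6L)
    recs[[i]]$defects <- c(recs[[i]]$defects, "length_outlier")
  }
  for (i in pick(rates$paralog_mislabel)) {
    g <- which(recs[[i]]$genes$gene == "tRNA-Leu(UUR)")
    recs[[i]]$genes$product[g] <- "tRNA-Leu(CUN)"
    recs[[i]]$defects <- c(recs[[i]]$defects, "paralog_mislabel")
  }
  recs
}

# build GenBank text + truth tables from the record list
assemble_panel <- function(recs) {
  spacer <- .spacer()
  gb <- character(0)
  gene_rows <- list()
  rec_rows <- list()
  allele_rows <- list()
  for (rec in recs) {
    pos <- nchar(spacer) + 1L
    seq_parts <- list(spacer)
    feats <- character(0)
    for (g in seq_len(nrow(rec$genes))) {
      s <- rec$genes$sequence[g]
      len <- nchar(s)
      genome_piece <- if (rec$genes$strand[g] == "-") revcomp(s) else s
      start <- pos; end <- pos + len - 1L
      loc <- if (rec$genes$strand[g] == "-") {
        sprintf("complement(%d..%d)", start, end)
      } else {
        sprintf("%d..%d", start, end)
      }
      feats <- c(feats,
                 sprintf("     tRNA            %s", loc),
                 sprintf("                     /product=\"%s\"",
                         rec$genes$product[g]))
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        accession = rec$accession, species = rec$species,
        gene = rec$genes$gene[g], product = rec$genes$product[g],
        start = start, end = end, strand = rec$genes$strand[g],
        sequence = s, stringsAsFactors = FALSE)
      seq_parts[[length(seq_parts) + 1L]] <- genome_piece
      seq_parts[[length(seq_parts) + 1L]] <- spacer
      pos <- end + nchar(spacer) + 1L
    }
    genome <- paste(unlist(seq_parts), collapse = "")
    rec_rows[[length(rec_rows) + 1L]] <- data.frame(
      accession = rec$accession, species = rec$species,
      defects = paste(rec$defects, collapse = ","),
      stringsAsFactors = FALSE)
    for (p in names(rec$alleles)) {
      allele_rows[[length(allele_rows) + 1L]] <- data.frame(
        accession = rec$accession, species = rec$species,
        position = as.integer(p), allele = rec$alleles[[p]],
        stringsAsFactors = FALSE)
    }
    gb <- c(gb, format_genbank_record(rec, genome, feats))
  }
  list(
    genbank = paste(gb, collapse = "\n"),
    truth = list(
      records = do.call(rbind, rec_rows),
      genes = do.call(rbind, gene_rows),
      alleles = if (length(allele_rows)) do.call(rbind, allele_rows) else
        data.frame(accession = character(0), species = character(0),
                   position = integer(0), allele = character(0))
    )
  )
}

format_genbank_record <- function(rec, genome, feats) {
  n <- nchar(genome)
  header <- c(
    sprintf("LOCUS       %s%17d bp    DNA     circular VRT 01-JAN-2020",
            rec$accession, n),
    sprintf("DEFINITION  %s mitochondrion, synthetic mini-genome.",
            rec$species),
    sprintf("ACCESSION   %s", rec$accession),
    sprintf("VERSION     %s.1", rec$accession),
    sprintf("SOURCE      mitochondrion %s", rec$species),
    sprintf("  ORGANISM  %s", rec$species),
    sprintf("            %s.", paste(rec$lineage, collapse = "; ")),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    sprintf("                     /organism=\"%s\"", rec$species),
    feats,
    "ORIGIN      "
  )
  # 60 bases per line in 10-base groups
  starts <- seq(1L, n, by = 60L)
  seq_lines <- vapply(starts, function(s) {
    chunk <- substr(genome, s, min(s + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, paste(tolower(groups), collapse = " "))
  }, "")
  paste(c(header, seq_lines, "//"), collapse = "\n")
}
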