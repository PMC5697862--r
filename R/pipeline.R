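#' Build a pipeline run configuration
#'
#' @param input GenBank flat-file text or a path to one (or a directory of
#'   `.gb`/`.gbk` files).
#' @param catalogue_path Variant catalogue CSV/TSV (default: packaged
#'   Leu(UUR) catalogue).
#' @param rubric_path Rubric YAML (default: packaged rubric).
#' @param template_path Cloverleaf template YAML (default: packaged
#'   Leu(UUR) template).
#' @param out_dir Output directory for reports (created if needed); `NULL`
#'   skips file output and returns results in memory only.
#' @param qc [qc_params()].
#' @param align [align_params()].
#' @param taxon_rank_index 1-based index into each record's lineage used as
#'   the aggregation taxon (the synthetic panels put the order at index 5).
#' @param network_species Species whose Leu(UUR) panel feeds the haplotype
#'   network (default: the largest panel).
#' @param network_positions rCRS positions used as network characters
#'   (default: the positions polymorphic within `network_species`).
#' @param cooccurrence_target rCRS position anchoring the co-occurrence
#'   report (default 3243 if catalogued).
#' @param min_sequences Species with fewer post-QC sequences are flagged in
#'   the summary (but still processed).
#' @param seed Seed recorded in the summary for provenance.
#' @return List of class `mt_run_config`.
#' @export
run_config <- function(input,
                       catalogue_path = leu_catalogue_path(),
                       rubric_path = NULL,
                       template_path = NULL,
                       out_dir = NULL,
                       qc = qc_params(),
                       align = align_params(),
                       taxon_rank_index = 5L,
                       network_species = NULL,
                       network_positions = NULL,
                       cooccurrence_target = 3243L,
                       min_sequences = 30L,
                       seed = 1L) {
  for (p in c(catalogue_path, rubric_path, template_path)) {
    if (!is.null(p) && !file.exists(p)) stop("missing config file: ", p)
  }
  structure(list(input = input, catalogue_path = catalogue_path,
                 rubric_path = rubric_path, template_path = template_path,
                 out_dir = out_dir, qc = qc, align = align,
                 taxon_rank_index = taxon_rank_index,
                 network_species = network_species,
                 network_positions = network_positions,
                 cooccurrence_target = cooccurrence_target,
                 min_sequences = min_sequences, seed = seed),
            class = "mt_run_config")
}

#' Run the full screen: extract, QC, align, screen, structure, network
#'
#' Orchestrates the whole analysis over the catalogue's gene: parses the
#' GenBank input, extracts and paralog-disambiguates tRNA genes, applies
#' QC, builds one reference-anchored alignment per species, screens every
#' catalogue variant, aggregates carrier frequencies by taxon, reports
#' co-occurrence of the target variant with the other catalogued positions,
#' assesses each variant's structural impact on the reference molecule, and
#' builds a haplotype network for the chosen species. All outputs are
#' deterministic for a fixed input and configuration.
#'
#' @param config [run_config()].
#' @return List of class `mt_run_result` with `summary` (stage counts and
#'   headline numbers), `genes`, `qc_report`, `screen`, `taxon_freq`,
#'   `cooccurrence`, `structure`, `haplotypes`, `network`, `panels`.
#'   When `out_dir` is set, TSV/JSON/FASTA reports are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mt_run_config"))
  template <- cloverleaf_template(config$template_path)
  catalogue <- load_catalogue(config$catalogue_path, template = template)
  gene <- unique(catalogue$gene)
  if (length(gene) != 1L) {
    stop("run_pipeline screens one gene per run; catalogue lists: ",
         paste(gene, collapse = ", "))
  }
  input <- config$input
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      dir.exists(input)) {
    files <- list.files(input, pattern = "\\.(gb|gbk|genbank)$",
                        full.names = TRUE)
    if (!length(files)) stop("no GenBank files found in ", input)
    input <- paste(vapply(files, function(f) {
      paste(readLines(f, warn = FALSE), collapse = "\n")
    }, ""), collapse = "\n")
  }
  records <- parse_genbank(input)
  if (!length(records)) stop("no GenBank records in input")
  genes <- do.call(rbind, lapply(records, extract_trna_genes))
  genes <- disambiguate_paralogs(genes)
  lineage_by_species <- tapply(genes$lineage, genes$species, `[`, 1L)
  target_genes <- genes[genes$gene == gene & is.na(genes$review_reason) &
                          !genes$paralog_review, , drop = FALSE]
  if (!nrow(target_genes)) stop("no ", gene, " records found in input")
  ref <- if (gene == "tRNA-Leu(UUR)") rcrs_leu_uur() else template$reference
  qc_res <- qc_filter(target_genes, ref, config$qc)
  passed <- qc_res$passed
  if (!nrow(passed)) stop("no records passed QC")
  skipped <- setdiff(unique(target_genes$species), unique(passed$species))
  for (sp in skipped) warning("species skipped (no post-QC records): ", sp)

  panels <- list()
  for (sp in unique(passed$species)) {
    sub <- passed[passed$species == sp, , drop = FALSE]
    seqs <- stats::setNames(sub$sequence, sub$accession)
    panels[[sp]] <- anchor_msa(ref, seqs, gene = gene,
                               params = config$align)
  }
  screen <- screen_variants(panels, catalogue)
  screen <- screen_percentages(screen)

  taxa <- vapply(names(panels), function(sp) {
    lin <- strsplit(lineage_by_species[[sp]], ";\\s*")[[1]]
    if (length(lin) >= config$taxon_rank_index) {
      lin[config$taxon_rank_index]
    } else {
      NA_character_
    }
  }, "")
  taxon_freq <- do.call(rbind, lapply(unique(catalogue$position), function(p) {
    cells <- screen[screen$position == p, , drop = FALSE]
    agg <- aggregate_by_taxon(cells, taxa)
    agg$position <- p
    agg
  }))

  cooc <- NULL
  tpos <- config$cooccurrence_target
  if (!is.null(tpos) && tpos %in% catalogue$position) {
    target <- catalogue[catalogue$position == tpos, , drop = FALSE][1, ]
    candidates <- catalogue[catalogue$position != tpos, , drop = FALSE]
    cooc <- do.call(rbind, lapply(names(panels), function(sp) {
      tab <- cooccurrence(panels[[sp]], target, candidates)$table
      tab$species <- sp
      tab
    }))
  }

  structure_rows <- lapply(seq_len(nrow(catalogue)), function(i) {
    v <- catalogue[i, ]
    if (v$gene != template$gene) return(NULL)
    imp <- assess_variant_structure(template$reference, v, template)
    data.frame(position = v$position, ref = v$ref, alt = v$alt,
               region = v$region,
               pairs_broken = nrow(imp$stem_pairs_broken),
               pairs_created = nrow(imp$stem_pairs_created),
               tertiary_touched = length(imp$tertiary_triplets_touched),
               stringsAsFactors = FALSE)
  })
  structure_tab <- do.call(rbind, structure_rows)

  net_sp <- config$network_species %||%
    names(panels)[which.max(vapply(panels, function(p) length(p$rows), 0L))]
  net_panel <- panels[[net_sp]]
  net_pos <- config$network_positions
  if (is.null(net_pos)) {
    rows <- do.call(rbind, strsplit(unname(net_panel$rows), ""))
    poly_cols <- which(apply(rows, 2L, function(x) {
      length(unique(x[x != "N"])) > 1L
    }))
    net_pos <- net_panel$rcrs_start - 1L +
      which(net_panel$column_of_rcrs %in% poly_cols)
  }
  haps <- NULL; net <- NULL; recurrence <- integer(0)
  if (length(net_pos)) {
    haps <- collapse_haplotypes(net_panel, net_pos)
    net <- median_joining(haps)
    recurrence <- tryCatch(detect_recurrence(net),
                           error = function(e) integer(0))
  }

  summary <- list(
    seed = config$seed,
    n_genbank_records = length(records),
    n_trna_genes = nrow(genes),
    n_target_gene = nrow(target_genes),
    n_post_qc = nrow(passed),
    n_species = length(panels),
    species_below_minimum = names(which(table(passed$species) <
                                          config$min_sequences)),
    skipped_species = skipped,
    network_species = if (length(net_pos)) net_sp else NULL,
    network_positions = net_pos,
    recurrent_positions = recurrence,
    screen_status_counts = as.list(table(screen$status))
  )

  result <- structure(list(summary = summary, genes = genes,
                           qc_report = qc_res$report,
                           qc_summary = attr(qc_res$report, "summary"),
                           screen = screen, taxon_freq = taxon_freq,
                           cooccurrence = cooc, structure = structure_tab,
                           haplotypes = haps, network = net,
                           panels = panels),
                      class = "mt_run_result")
  if (!is.null(config$out_dir)) write_run_result(result, config$out_dir)
  result
}

write_run_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  tsv(result$qc_report, "qc_report.tsv")
  tsv(result$qc_summary, "qc_summary.tsv")
  tsv(result$screen, "screen.tsv")
  tsv(result$taxon_freq, "taxon_frequencies.tsv")
  if (!is.null(result$cooccurrence)) {
    tsv(result$cooccurrence, "cooccurrence.tsv")
  }
  tsv(result$structure, "structure_impact.tsv")
  fasta_dir <- file.path(out_dir, "fasta")
  dir.create(fasta_dir, showWarnings = FALSE)
  for (sp in names(result$panels)) {
    panel <- result$panels[[sp]]
    df <- data.frame(accession = names(panel$rows),
                     species = sp, gene = panel$gene %||% "gene",
                     sequence = gsub("-", "", unname(panel$rows),
                                     fixed = TRUE),
                     stringsAsFactors = FALSE)
    safe <- gsub("[^A-Za-z0-9]+", "_", sp)
    write_gene_fasta(df, file.path(fasta_dir, paste0(safe, ".fasta")))
  }
  if (!is.null(result$haplotypes)) {
    hd <- data.frame(label = result$haplotypes$label,
                     result$haplotypes$alleles,
                     count = result$haplotypes$count, check.names = FALSE,
                     stringsAsFactors = FALSE)
    tsv(hd, "haplotypes.tsv")
  }
  if (!is.null(result$network)) {
    write_network(result$network, file.path(out_dir, "network.tsv"), "tsv")
    write_network(result$network, file.path(out_dir, "network.graphml"),
                  "graphml")
  }
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
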