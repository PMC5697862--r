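make_sim <- function(n = 3, defects = list(), seed = 42, ...) {
  simulate_panel(toy_config(toy_species(n = n, ...), defects = defects,
                            seed = seed))
}

test_that("parser round-trips the generator's records and features", {
  sim <- make_sim(n = 3)
  recs <- parse_genbank(sim$genbank)
  expect_length(recs, 3L)
  expect_equal(vapply(recs, `[[`, "", "accession"),
               c("SYN00001", "SYN00002", "SYN00003"))
  r <- recs[[1]]
  expect_equal(r$organism, "Testus species")
  expect_equal(r$lineage[5], "Testorder")
  expect_equal(sum(r$features$kind == "tRNA"), 6L)
  # complement() locations carry the minus strand
  gln <- r$features[which(r$features$product == "tRNA-Gln"), ]
  expect_equal(gln$strand, "-")
  # intervals sit inside the sequence and match the truth table
  truth <- sim$truth$genes[sim$truth$genes$accession == "SYN00001", ]
  tr <- r$features[r$features$kind == "tRNA", ]
  expect_equal(tr$start, truth$start)
  expect_equal(tr$end, truth$end)
})

test_that("parser reports missing sections by record", {
  sim <- make_sim(n = 1)
  txt <- strsplit(sim$genbank, "\n")[[1]]
  expect_error(parse_genbank(c(txt[!grepl("^ORIGIN", txt)])),
               "SYN00001.*missing ORIGIN")
  no_feat <- txt[!grepl("^FEATURES", txt)]
  expect_error(parse_genbank(no_feat), "SYN00001.*missing FEATURES")
  expect_error(parse_genbank("LOCUS X"), "terminator")
})

test_that("extraction reproduces the generator truth, including strand", {
  sim <- make_sim(n = 5, background = c("3243" = "G"))
  recs <- parse_genbank(sim$genbank)
  genes <- do.call(rbind, lapply(recs, extract_trna_genes))
  truth <- sim$truth$genes
  # every truth gene is recovered with the exact coding-sense sequence
  merged <- merge(truth, genes, by = c("accession", "gene"))
  expect_equal(nrow(merged), nrow(truth))
  expect_equal(merged$sequence.y, merged$sequence.x)
  # the minus-strand genes were reverse-complemented (oracle: Biostrings)
  minus <- merged[merged$strand.x == "-", ][1, ]
  rec <- recs[[match(minus$accession, vapply(recs, `[[`, "", "accession"))]]
  raw <- substr(rec$sequence, minus$start.x, minus$end.x)
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(raw))), minus$sequence.x)
})

test_that("records without tRNA features yield an empty set with a warning", {
  sim <- make_sim(n = 1)
  rec <- parse_genbank(sim$genbank)[[1]]
  rec$features <- rec$features[rec$features$kind != "tRNA", , drop = FALSE]
  expect_warning(out <- extract_trna_genes(rec), "no tRNA features")
  expect_equal(nrow(out), 0L)
})

test_that("features lacking a product label are review-routed, not guessed", {
  sim <- make_sim(n = 1)
  txt <- sub("/product=\"tRNA-Phe\"", "/product=\"tRNA-Mystery\"",
             sim$genbank, fixed = TRUE)
  rec <- parse_genbank(txt)[[1]]
  expect_warning(out <- extract_trna_genes(rec), "review")
  expect_equal(sum(!is.na(out$review_reason)), 1L)
  expect_true(is.na(out$gene[!is.na(out$review_reason)]))
})

test_that("paralogs are assigned by identity and ties go to review", {
  refs <- paralog_references()
  base <- data.frame(
    accession = c("A1", "A2", "A3", "A4"),
    species = "Testus species", lineage = "",
    gene = c("tRNA-Leu", "tRNA-Leu", "tRNA-Phe", "tRNA-Ser"),
    sequence = c(refs[["tRNA-Leu(UUR)"]], refs[["tRNA-Leu(CUN)"]],
                 "GTTTATGTAGCTTAACTCAAAGCAAGGCACTGAAAATGCCTAGATGAGT",
                 refs[["tRNA-Ser(AGY)"]]),
    start = 1L, end = 10L, strand = "+", review_reason = NA_character_,
    stringsAsFactors = FALSE)
  out <- disambiguate_paralogs(base)
  expect_equal(out$gene, c("tRNA-Leu(UUR)", "tRNA-Leu(CUN)", "tRNA-Phe",
                           "tRNA-Ser(AGY)"))
  expect_false(any(out$paralog_review))
  # unambiguous gene passed through untouched
  expect_false(out$paralog_assigned[3])

  # a specific but wrong label is corrected
  swapped <- base[1, ]
  swapped$gene <- "tRNA-Leu(CUN)"
  out <- disambiguate_paralogs(swapped)
  expect_equal(out$gene, "tRNA-Leu(UUR)")
  expect_true(out$paralog_assigned)

  # an exact tie cannot be decided: review bucket
  tie <- base[1, ]
  tie$sequence <- "ACGTACGTACGTACGTACGT"
  uur <- substr(refs[["tRNA-Leu(UUR)"]], 1, 20)
  fake_refs <- c("tRNA-Leu(UUR)" = "ACCTACGTACGTACGTACGT",
                 "tRNA-Leu(CUN)" = "ACGTACGTACGTACGTACCT",
                 refs[c("tRNA-Ser(UCN)", "tRNA-Ser(AGY)")])
  out <- disambiguate_paralogs(tie, refs = fake_refs)
  expect_true(out$paralog_review)
  expect_equal(out$gene, "tRNA-Leu")
})

test_that("paralog assignment is perfect on a panel with distinct paralogs", {
  # generic "tRNA-Leu" labels across a panel: every record must come back
  # as Leu(UUR), since the panel's Leu genes derive from the UUR reference
  sim <- make_sim(n = 8)
  txt <- gsub("/product=\"tRNA-Leu(UUR)\"", "/product=\"tRNA-Leu\"",
              sim$genbank, fixed = TRUE)
  txt <- gsub("/product=\"tRNA-Leu(CUN)\"", "/product=\"tRNA-Leu\"",
              txt, fixed = TRUE)
  genes <- extract_panel_genes(list(genbank = txt))
  truth <- sim$truth$genes
  merged <- merge(truth[grepl("Leu", truth$gene), ],
                  genes[grepl("Leu", genes$gene), ],
                  by = c("accession", "sequence"))
  expect_equal(nrow(merged), 16L) # 2 Leu genes x 8 records
  expect_equal(merged$gene.y, merged$gene.x)
})

test_that("gene FASTA round-trips through the header convention", {
  df <- data.frame(accession = c("X1", "X2"), species = "Testus species",
                   gene = "tRNA-Leu(UUR)",
                   sequence = c(rcrs_leu_uur(), rcrs_leu_uur()),
                   stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_gene_fasta(df, tmp)
  back <- read_gene_fasta(tmp)
  expect_equal(back$accession, df$accession)
  expect_equal(back$gene, df$gene)
  expect_equal(back$sequence, df$sequence)
})
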