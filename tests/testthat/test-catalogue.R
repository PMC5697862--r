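test_that("molecule positions convert with orientation awareness", {
  expect_equal(molecule_position(3243, "tRNA-Leu(UUR)"), 14L)
  expect_equal(molecule_position(3253, "tRNA-Leu(UUR)"), 24L)
  expect_equal(molecule_position(3230, "tRNA-Leu(UUR)"), 1L)
  expect_equal(molecule_position(3304, "tRNA-Leu(UUR)"), 75L)
  # light-strand gene: counted from the gene end
  glu <- rcrs_gene_table()
  row <- glu[glu$gene == "tRNA-Glu", ]
  expect_equal(molecule_position(row$end, "tRNA-Glu"), 1L)
  expect_equal(molecule_position(row$start, "tRNA-Glu"), row$length)
  expect_error(molecule_position(3229, "tRNA-Leu(UUR)"), "outside")
  expect_error(molecule_position(9999, "tRNA-Leu(UUR)"), "outside")
})

test_that("the packaged catalogue loads, validates and sorts", {
  tpl <- cloverleaf_template()
  cat_df <- load_catalogue(leu_catalogue_path(), template = tpl)
  expect_equal(nrow(cat_df), 32L)
  expect_false(is.unsorted(cat_df$position))
  expect_true(all(cat_df$gene == "tRNA-Leu(UUR)"))
  m3243 <- cat_df[cat_df$position == 3243, ]
  expect_equal(m3243$molecule_position, 14L)
  expect_equal(m3243$region, "d-loop")
  # the dog D-stem compensators are recorded with heavy-strand alleles
  expect_equal(cat_df$alt[cat_df$position == 3253], "C")
  expect_equal(cat_df$alt[cat_df$position == 3254], "T")
})

test_that("catalogue validation rejects malformed rows by name", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("position,ref,alt,gene,region,class",
               "3243,A,X,tRNA-Leu(UUR),d-loop,definitely"), tmp)
  expect_error(load_catalogue(tmp), "row 1.*malformed allele")
  writeLines(c("position,ref,alt,gene,region,class",
               "9999,A,G,tRNA-Leu(UUR),d-loop,definitely"), tmp)
  expect_error(load_catalogue(tmp), "outside the tRNA-Leu\\(UUR\\) span")
  writeLines(c("position,ref,alt,gene,region,class",
               "3243,A,G,tRNA-Leu(UUR),q-loop,definitely"), tmp)
  expect_error(load_catalogue(tmp), "unknown region")
  writeLines(c("position,ref,alt,gene,region,class",
               "3243,A,G,tRNA-Leu(UUR),d-loop,definitely",
               "3243,A,G,tRNA-Leu(UUR),d-loop,definitely"), tmp)
  expect_error(load_catalogue(tmp), "duplicate")
  # empty file with header is an empty catalogue, not an error
  writeLines("position,ref,alt,gene,region,class", tmp)
  expect_equal(nrow(load_catalogue(tmp)), 0L)
})

test_that("rubric classification reproduces the archetypal calls", {
  rub <- load_rubric()
  # m.3243A>G-like: many reports, conserved, heteroplasmic, segregating,
  # biochemical defect, single-fibre evidence
  ev <- pathogenicity_evidence(independent_reports = 10,
                               evolutionary_conservation = TRUE,
                               heteroplasmy = TRUE,
                               segregation_with_phenotype = TRUE,
                               biochemical_defect = TRUE,
                               single_fibre_evidence = TRUE)
  expect_equal(classify_variant(ev, rub), "definitely")
  # m.3290T>C-like: polymorphic in populations, limited evidence
  ev <- pathogenicity_evidence(independent_reports = 1)
  expect_equal(classify_variant(ev, rub), "neutral")
  expect_equal(classify_variant(pathogenicity_evidence(), rub), "neutral")
  # top-band score without functional evidence is demoted
  ev <- pathogenicity_evidence(independent_reports = 5,
                               evolutionary_conservation = TRUE,
                               heteroplasmy = TRUE,
                               segregation_with_phenotype = TRUE,
                               biochemical_defect = TRUE)
  expect_equal(classify_variant(ev, rub), "probably")
})

test_that("classification is monotone in the evidence", {
  rub <- load_rubric()
  fields <- c("evolutionary_conservation", "heteroplasmy",
              "segregation_with_phenotype", "biochemical_defect",
              "single_fibre_evidence", "cybrid_or_in_vitro_evidence")
  rank <- function(cl) match(cl, c("neutral", "possibly", "probably",
                                   "definitely"))
  set.seed(21)
  for (rep in 1:50) {
    flags <- sample(c(TRUE, FALSE), length(fields), replace = TRUE)
    args <- c(list(independent_reports = sample(0:5, 1)),
              stats::setNames(as.list(flags), fields))
    base_class <- classify_variant(do.call(pathogenicity_evidence, args), rub)
    off <- which(!flags)
    if (!length(off)) next
    add <- sample(off, 1)
    args2 <- args
    args2[[fields[add]]] <- TRUE
    more_class <- classify_variant(do.call(pathogenicity_evidence, args2), rub)
    expect_gte(rank(more_class), rank(base_class))
  }
})

test_that("with the gate off and degenerate bands, class is a pure report-count threshold", {
  rub <- rubric(weights = c(independent_reports = 1,
                            evolutionary_conservation = 0,
                            heteroplasmy = 0, segregation_with_phenotype = 0,
                            biochemical_defect = 0,
                            single_fibre_evidence = 0,
                            cybrid_or_in_vitro_evidence = 0),
                multi_report_threshold = 3,
                class_bands = c(possibly = 1, probably = 2),
                functional_gate = FALSE)
  for (n in 0:6) {
    ev <- pathogenicity_evidence(independent_reports = n)
    expect_equal(classify_variant(ev, rub),
                 if (n >= 3) "possibly" else "neutral")
  }
})

test_that("the packaged evidence table reproduces the catalogue class split", {
  ev <- utils::read.csv(leu_evidence_path())
  cl <- classify_evidence_table(ev)
  tally <- table(cl$class)
  expect_equal(unname(tally[["neutral"]]), 12L)
  expect_equal(unname(tally[["possibly"]]), 8L)
  expect_equal(unname(tally[["probably"]]), 1L)
  expect_equal(unname(tally[["definitely"]]), 11L)
  # and entry-by-entry agreement with the catalogue's stored classes
  cat_df <- load_catalogue(leu_catalogue_path())
  merged <- merge(cat_df, cl, by = "position", suffixes = c("_cat", "_scored"))
  expect_equal(merged$class_scored, merged$class_cat)
})

test_that("invalid rubrics are rejected", {
  expect_error(rubric(weights = c(independent_reports = -1),
                      class_bands = c(possibly = 1, probably = 2)),
               ">= 0")
  expect_error(rubric(weights = c(independent_reports = 1),
                      class_bands = c(possibly = 5, probably = 5)),
               "increasing")
})
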