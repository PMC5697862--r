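tpl <- cloverleaf_template()
ref <- rcrs_leu_uur()

mutate_mol <- function(s, mol, allele) {
  v <- strsplit(s, "")[[1]]
  v[mol] <- allele
  paste(v[v != "-"], collapse = "")
}

test_that("pair classes follow the Watson-Crick / wobble rules", {
  expect_equal(pair_class("A", "T"), "watson_crick")
  expect_equal(pair_class("T", "A"), "watson_crick")
  expect_equal(pair_class("G", "C"), "watson_crick")
  expect_equal(pair_class("C", "G"), "watson_crick")
  expect_equal(pair_class("G", "T"), "wobble")
  expect_equal(pair_class("T", "G"), "wobble")
  expect_equal(pair_class("A", "C"), "mismatch")
  expect_equal(pair_class("A", "A"), "mismatch")
  expect_equal(pair_class("N", "T"), "unknown")
  expect_equal(pair_class("-", "T"), "unknown")
})

test_that("the template is an involution with consistent regions", {
  paired <- which(!is.na(tpl$partner))
  expect_equal(tpl$partner[tpl$partner[paired]], paired)
  expect_equal(tpl$length, 75L)
  # every catalogued region label matches the template at that position
  cat_df <- load_catalogue(leu_catalogue_path())
  expect_equal(region_of_position(tpl, cat_df$molecule_position),
               cat_df$region)
  expect_equal(nchar(dot_bracket(tpl)), 75L)
})

test_that("reference D-stem shows 2 WC + 1 wobble + 2 unpaired nucleotides", {
  ann <- annotate_cloverleaf(ref, tpl)
  rep <- stem_report(ann, "d-stem")
  expect_equal(rep[["watson_crick"]], 2L)
  expect_equal(rep[["wobble"]], 1L)
  expect_equal(rep[["mismatch"]], 1L)
  expect_equal(rep[["unpaired_nucleotides"]], 2L)
  # the wobble sits adjacent to the d-loop (pair 13:24)
  w <- ann[ann$region == "d-stem" & ann$pair_class == "wobble", ]
  expect_equal(c(w$pos5, w$pos3), c(13L, 24L))
})

test_that("dog-like D-stem substitutions create two extra WC pairs", {
  dog <- mutate_mol(mutate_mol(ref, 24, "C"), 25, "T")
  rep <- stem_report(annotate_cloverleaf(dog, tpl), "d-stem")
  expect_equal(rep[["watson_crick"]], 4L)
  expect_equal(rep[["wobble"]], 0L)
  expect_equal(rep[["mismatch"]], 0L)
})

test_that("an all-A toy sequence has only mismatched stem pairs", {
  allA <- paste(rep("A", 75), collapse = "")
  ann <- annotate_cloverleaf(allA, tpl)
  expect_true(all(ann$pair_class == "mismatch"))
})

test_that("3243A>G touches its tertiary triple and no stem pair", {
  cat_df <- load_catalogue(leu_catalogue_path())
  v <- cat_df[cat_df$position == 3243, ]
  imp <- assess_variant_structure(ref, v, tpl)
  expect_equal(nrow(imp$stem_pairs_broken), 0L)
  expect_equal(nrow(imp$stem_pairs_created), 0L)
  expect_length(imp$tertiary_triplets_touched, 1L)
  expect_equal(imp$tertiary_triplets_touched[[1]], c(8L, 14L, 21L))
  expect_false(imp$compensated)
})

test_that("3271T>C breaks the ac-stem A-T pair; a partner change compensates", {
  cat_df <- load_catalogue(leu_catalogue_path())
  v <- cat_df[cat_df$position == 3271, ]
  imp <- assess_variant_structure(ref, v, tpl)
  expect_equal(nrow(imp$stem_pairs_broken), 1L)
  expect_equal(imp$stem_pairs_broken$region, "ac-stem")
  expect_equal(imp$stem_pairs_broken$pair_class, "watson_crick")
  # fish-like background: the partner position 30 carries G, pair reads C-G
  fish <- mutate_mol(mutate_mol(ref, 42, "C"), 30, "G")
  imp <- assess_variant_structure(ref, v, tpl, background = fish)
  expect_true(imp$compensated)
  expect_equal(imp$compensating_positions, 30L)
  # on the bare human reference, nothing compensates
  imp <- assess_variant_structure(ref, v, tpl, background = ref)
  expect_false(imp$compensated)
})

test_that("every stem variant in the catalogue is compensated by its partner change", {
  cat_df <- load_catalogue(leu_catalogue_path())
  stems <- cat_df[cat_df$region %in% c("acc-stem", "d-stem", "ac-stem",
                                       "t-stem"), ]
  for (i in seq_len(nrow(stems))) {
    v <- stems[i, ]
    imp <- assess_variant_structure(ref, v, tpl)
    if (!nrow(imp$stem_pairs_broken)) next
    partner <- tpl$partner[v$molecule_position]
    # background carrying the exact complementary change at the partner
    comp_base <- chartr("ACGT", "TGCA", v$alt)
    bg <- mutate_mol(mutate_mol(ref, v$molecule_position, v$alt),
                     partner, comp_base)
    imp_bg <- assess_variant_structure(ref, v, tpl, background = bg)
    expect_true(imp_bg$compensated, info = paste("position", v$position))
    imp_ref <- assess_variant_structure(ref, v, tpl, background = ref)
    expect_false(imp_ref$compensated, info = paste("position", v$position))
  }
})

test_that("bear-like background reports the tertiary 46 substitution for 3251", {
  cat_df <- load_catalogue(leu_catalogue_path())
  v <- cat_df[cat_df$position == 3251, ]
  bear <- mutate_mol(mutate_mol(ref, 22, "G"), 46, "T")
  imp <- assess_variant_structure(ref, v, tpl, background = bear)
  expect_true(any(vapply(imp$tertiary_triplets_touched,
                         function(tr) all(c(13L, 22L, 46L) %in% tr), TRUE)))
  expect_true(imp$compensated)
  expect_equal(imp$compensating_positions, 46L)
})

test_that("variant application is reversible and checks the ref allele", {
  cat_df <- load_catalogue(leu_catalogue_path())
  v <- cat_df[cat_df$position == 3271, ]
  mutated <- mutate_mol(ref, v$molecule_position, v$alt)
  back <- v
  back$ref <- v$alt
  back$alt <- v$ref
  imp_fwd <- assess_variant_structure(ref, v, tpl)
  imp_back <- assess_variant_structure(mutated, back, tpl)
  expect_equal(imp_back$pairs_after$pair_class,
               imp_fwd$pairs_before$pair_class)
  expect_error(assess_variant_structure(mutated, v, tpl),
               "does not match")
})

test_that("indel-bearing sequences annotate through template anchoring", {
  # deletion in the d-loop: stem annotations survive, gap positions unknown
  del <- paste0(substr(ref, 1, 15), substr(ref, 17, 75))
  ann <- annotate_cloverleaf(del, tpl)
  expect_equal(stem_report(ann, "d-stem")[["watson_crick"]], 2L)
  expect_equal(stem_report(ann, "ac-stem"),
               stem_report(annotate_cloverleaf(ref, tpl), "ac-stem"))
  expect_warning(annotate_cloverleaf(substr(ref, 1, 60), tpl),
                 "more than 5")
})
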