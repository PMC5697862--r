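test_that("global alignment matches hand-checked small cases", {
  a <- global_align("ACGT", "ACGT")
  expect_equal(a$alignment_length, 4L)
  expect_equal(a$identities, 4L)

  a <- global_align("ACGT", "AGT")
  expect_equal(a$identities, 3L)
  expect_equal(nchar(a$a), 4L)
  expect_equal(sum(strsplit(a$b, "")[[1]] == "-"), 1L)

  expect_error(global_align("", "ACGT"), "empty")
})

test_that("alignment score equals the exhaustive-enumeration oracle", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:40) {
    a <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b)$score,
                 brute_force_align_score(a, b),
                 info = paste(a, b))
  }
  # the fully-reversed pair from the worked example set
  expect_equal(global_align("ACGT", "TGCA")$score,
               brute_force_align_score("ACGT", "TGCA"))
})

test_that("alignment score agrees with an independent overlap aligner", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(12)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:15) {
    a <- paste(sample(bases, sample(8:20, 1), replace = TRUE), collapse = "")
    b <- paste(sample(bases, sample(8:20, 1), replace = TRUE), collapse = "")
    ref_score <- Biostrings::pairwiseAlignment(
      a, b, type = "overlap", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(global_align(a, b)$score, ref_score, info = paste(a, b))
  }
})

test_that("percent identity follows the identities / alignment-length rule", {
  ref <- rcrs_leu_uur()
  expect_equal(percent_identity(global_align(ref, ref)), 100)
  expect_equal(percent_identity(global_align("ACGTACGTAC", "ACGTATTTTC")), 70)
  # 20 substitutions over the 75-nt gene: the amphibian worked example
  amph <- as.character(Biostrings::readDNAStringSet(
    system.file("extdata", "scolecomorphus_like_synthetic.fasta",
                package = "mttrnascreen")))
  aln <- global_align(ref, amph)
  expect_equal(aln$alignment_length, 75L)
  expect_equal(aln$identities, 55L)
  expect_equal(percent_identity(aln), 73.33)
})

test_that("percent identity is row-symmetric and reverse-complement invariant", {
  # the statistic is a function of the aligned rows: swapping them or
  # reverse-complementing both leaves it unchanged
  rc_row <- function(x) {
    v <- rev(strsplit(x, "")[[1]])
    paste(chartr("ACGT", "TGCA", v), collapse = "")
  }
  recount <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    structure(list(a = a, b = b, alignment_length = length(av),
                   identities = sum(av == bv & av != "-" & av != "N"),
                   score = NA_real_), class = "mt_alignment")
  }
  set.seed(13)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:10) {
    a <- paste(sample(bases, 30, replace = TRUE), collapse = "")
    b <- paste(sample(bases, 30, replace = TRUE), collapse = "")
    aln <- global_align(a, b)
    pid <- percent_identity(aln)
    expect_equal(percent_identity(recount(aln$b, aln$a)), pid)
    expect_equal(percent_identity(recount(rc_row(aln$a), rc_row(aln$b))),
                 pid)
  }
})

test_that("N is never an identity", {
  aln <- global_align("AANAA", "AANAA")
  expect_equal(aln$alignment_length, 5L)
  expect_equal(aln$identities, 4L)
})

test_that("anchored alignment maps rCRS positions through gaps", {
  ref <- rcrs_leu_uur()
  # identical member: identity map
  msa <- anchor_msa(ref, c(x = ref), gene = "tRNA-Leu(UUR)")
  expect_equal(msa$ncol, 75L)
  expect_equal(rcrs_to_column(msa, 3243), 14L)
  expect_equal(msa$column_of_rcrs, 1:75)

  # member with a deletion at molecule position 10 (the 3239 equivalent)
  del <- paste0(substr(ref, 1, 9), substr(ref, 11, 75))
  msa <- anchor_msa(ref, c(d = del), gene = "tRNA-Leu(UUR)")
  col <- rcrs_to_column(msa, 3239)
  expect_equal(substr(msa$rows[["d"]], col, col), "-")

  # member with an insertion before molecule position 14 shifts 3243 by one
  ins <- paste0(substr(ref, 1, 12), "A", substr(ref, 13, 75))
  msa <- anchor_msa(ref, c(i = ins, x = ref), gene = "tRNA-Leu(UUR)")
  expect_equal(rcrs_to_column(msa, 3243), 15L)
  expect_equal(substr(msa$ref_row, rcrs_to_column(msa, 3243),
                      rcrs_to_column(msa, 3243)), "A")
  expect_error(rcrs_to_column(msa, 3229), "outside")
})

test_that("reference round trip holds on random gapped alignments", {
  set.seed(14)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:200) {
    n <- sample(20:40, 1)
    ref <- paste(sample(bases, n, replace = TRUE), collapse = "")
    members <- lapply(1:3, function(k) {
      s <- strsplit(ref, "")[[1]]
      # substitutions
      at <- sample(n, sample(0:3, 1))
      s[at] <- sample(bases, length(at), replace = TRUE)
      # one random indel
      if (runif(1) < 0.5) {
        p <- sample(2:(n - 1), 1)
        if (runif(1) < 0.5) s <- s[-p] else s <- append(s, sample(bases, 1), p)
      }
      paste(s, collapse = "")
    })
    names(members) <- paste0("m", 1:3)
    msa <- anchor_msa(ref, unlist(members), rcrs_start = 1L)
    expect_equal(gsub("-", "", msa$ref_row, fixed = TRUE), ref)
    rv <- strsplit(msa$ref_row, "")[[1]]
    expect_equal(paste(rv[msa$column_of_rcrs], collapse = ""), ref)
    expect_true(all(diff(msa$column_of_rcrs) >= 1))
    expect_true(all(nchar(msa$rows) == msa$ncol))
  }
})

test_that("low-identity members are aligned but flagged", {
  ref <- rcrs_leu_uur()
  junk <- paste(rep("C", 75), collapse = "")
  msa <- anchor_msa(ref, c(ok = ref, bad = junk), gene = "tRNA-Leu(UUR)")
  expect_equal(msa$flagged, "bad")
})

test_that("zero-length alignment is rejected by percent_identity", {
  fake <- structure(list(a = "", b = "", alignment_length = 0L,
                         identities = 0L, score = 0),
                    class = "mt_alignment")
  expect_error(percent_identity(fake), "zero-length")
})
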