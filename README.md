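# mttrnascreen

Cross-species screening of human disease-associated mitochondrial tRNA
variants.

## The problem

Human mtDNA disease mutations cluster in the 22 mt-tRNA genes; the most
common, m.3243A>G in mt-tRNA-Leu(UUR), causes MELAS and related syndromes.
Yet alleles that are pathogenic in humans sometimes segregate as the *major
population variant* in other chordate species — dogs, bears, seals, old-world
monkeys — with no sign of disease. When that happens, the species' sequence
background often carries a second substitution that restores the tRNA's
cloverleaf secondary structure (e.g. re-forming a Watson–Crick stem pair
broken by the mutation) or alters a long-range tertiary interaction. Finding
such variants and their putative compensators speaks directly to how
haplogroup context modulates penetrance, and to why mutation catalogues built
from European cohorts transfer poorly to other populations.

`mttrnascreen` is an R toolkit for this comparative screen. For users in
molecular evolution and mitochondrial genetics it provides:

- **GenBank extraction** — a flat-file reader for annotated mitochondrial
  genomes, tRNA gene extraction with strand normalization, and
  percent-identity disambiguation of the duplicated Leu(UUR)/Leu(CUN) and
  Ser(UCN)/Ser(AGY) paralogs (`parse_genbank()`, `extract_trna_genes()`,
  `disambiguate_paralogs()`).
- **Quality control** — length-deviation, ambiguous-base (N) and
  within-species similarity checks with pass/review/removed dispositions
  (`qc_filter()`, `similarity_outliers()`).
- **Reference-anchored alignment** — Needleman–Wunsch pairwise alignment
  merged into a star alignment anchored on the rCRS gene, with a gap-aware
  map from every rCRS coordinate to its alignment column
  (`global_align()`, `anchor_msa()`, `rcrs_to_column()`).
- **Variant screening** — per-species carrier counts, frequencies and
  monomorphic/polymorphic status for a catalogued variant set; taxonomic
  aggregation; co-occurrence of a target variant with candidate compensators
  (`screen_variants()`, `aggregate_by_taxon()`, `cooccurrence()`).
- **Pathogenicity classification** — a configurable point-based rubric
  (reports, conservation, heteroplasmy, segregation, biochemistry, gated on
  single-fibre/cybrid evidence) scoring variants as
  neutral/possibly/probably/definitely pathogenic (`classify_variant()`).
- **Cloverleaf structure analysis** — template-based annotation of the four
  stems with Watson–Crick/wobble/mismatch pair classes, variant impact
  assessment, and compensation detection against a background sequence
  (`annotate_cloverleaf()`, `assess_variant_structure()`).
- **Haplotype networks** — haplotype collapsing, a median-joining network
  with deterministic output, and recurrent-mutation (reticulation) detection
  (`collapse_haplotypes()`, `median_joining()`, `detect_recurrence()`).
- **Synthetic panels** — a GenBank mini-genome generator with exact-count
  variant injection, linked compensators, plantable QC defects and a full
  truth table, so the entire pipeline is testable offline
  (`simulate_panel()`, `degrade()`).

`run_pipeline()` orchestrates extract → QC → align → screen → structure →
network and writes TSV/JSON/FASTA reports.

## Worked example

Simulate the packaged 391-record dog panel — whose Leu(UUR) haplotype groups
mirror the published dog phylogeny table — and run the full screen:

```r
library(mttrnascreen)

sim <- simulate_panel(load_panel_config(panel_preset_path("dog")), seed = 1)
res <- run_pipeline(run_config(sim$genbank,
                               network_positions = c(3230, 3239, 3243, 3290)))

sc <- res$screen
sc[sc$position %in% c(3243, 3253) & sc$carriers > 0,
   c("position", "alt", "carriers", "total", "status", "percent")]
#>    position alt carriers total      status percent
#> 4      3243   G       57   391 polymorphic      15
#> 10     3253   C      391   391 monomorphic     100

res$cooccurrence[res$cooccurrence$candidate_position == 3253,
                 c("both", "target_only", "pct_target_with_candidate")]
#>   both target_only pct_target_with_candidate
#> 1   57           0                       100

data.frame(res$haplotypes$alleles, count = res$haplotypes$count)
#>   X3230 X3239 X3243 X3290 count
#> 1     G     G     A     T   328
#> 2     G     G     G     T    55
#> 3     G     -     A     T     3
#> 4     G     -     G     T     2
#> 5     G     G     A     C     2
#> 6     -     G     A     A     1

res$summary$recurrent_positions
#> [1] 3239 3243
```

Reading: m.3243A>G is carried by 57/391 (15%) of dog sequences and every
carrier also carries the D-stem substitution 3253C, which converts the
stem's G–U wobble pair into a Watson–Crick pair — the compensation
hypothesis. 3253C itself is fixed (monomorphic) in the panel. The haplotype
network reproduces the six groups with the 328-sequence group as the
ancestral candidate, and its reticulation shows that the changes at
positions 3239 and 3243 each arose more than once.

Structure queries work directly on the packaged Leu(UUR) template:

```r
tpl <- cloverleaf_template()
stem_report(annotate_cloverleaf(rcrs_leu_uur(), tpl), "d-stem")
#> watson_crick  wobble  mismatch  unknown  unpaired_nucleotides
#>            2       1         1        0                     2
```

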