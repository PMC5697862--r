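---
title: "Screening disease-associated mt-tRNA variants across species: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening disease-associated mt-tRNA variants across species: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mttrnascreen)
```

This vignette is the package's account of its methods: the model behind each
stage, the parameters that matter, the numerical choices, and the limits of
what the synthetic panels can demonstrate.

## The screen

The question the package operationalizes is: *do alleles that cause
mitochondrial disease in humans segregate as normal variants in other
chordates, and if so, does the species' background carry substitutions that
plausibly compensate for them?* The analysis proceeds per species:

1. extract the annotated mt-tRNA genes from complete mitochondrial genomes
   (GenBank flat files),
2. quality-control the extracted gene sequences,
3. align each species panel to the human reference (rCRS) copy of the gene,
4. read the alignment columns at catalogued disease-associated positions and
   classify each species x variant cell as absent, polymorphic or
   monomorphic,
5. ask whether carriers of a target variant also carry candidate
   compensators (co-occurrence), and whether those compensators restore the
   cloverleaf secondary structure (template annotation),
6. summarize within-species variation as a median-joining haplotype network.

All genome coordinates are rCRS positions (the 16,569-bp human reference);
per-species coordinates never appear downstream of extraction because every
position is mapped through the gene-relative *molecule position* (rCRS 3243
is position 14 of the 75-nt tRNA-Leu(UUR) gene at 3230..3304). Light-strand
genes are reverse-complemented at extraction, and their molecule positions
count from the gene's 3' genome end, so the catalogue's heavy-strand alleles
apply uniformly.

## Extraction and paralog disambiguation

The GenBank reader is deliberately minimal: LOCUS/ACCESSION, the ORGANISM
line and its taxonomy continuation, tRNA features with `a..b`,
`complement()` and `join()` locations, `/product` qualifiers, and the ORIGIN
block. Species identity is the ORGANISM line verbatim, which keeps
subspecies distinct. Product labels are normalized through a packaged,
editable mapping; a feature with an unknown or missing product is routed to
a review list with a warning, never guessed.

mtDNA carries two tRNA-Leu and two tRNA-Ser genes. Records labelled
generically ("tRNA-Leu"), or with a specific label that may be wrong, are
scored by percent identity against both paralog references and assigned to
the better one; exact ties go to review. Only the Leu(UUR) reference is the
true rCRS gene — the three other paralog references shipped with the package
are synthetic rCRS-like stand-ins (so documented), which is sufficient
because assignment only needs the paralogs to be mutually distinct.

## Quality control

Three checks, mirroring standard practice for uncurated GenBank material:

- **Ambiguous bases**: more than `max_n` (default 5) Ns → *removed*.
- **Length**: more than `length_tolerance` (default 5 nt) longer or shorter
  than the reference gene → *review*. The original workflow examined such
  sequences manually; a pipeline cannot be interactive, so review records
  are excluded from downstream frequency math by default, with
  `auto_exclude_length_outliers` available to remove them outright.
- **Similarity**: each record's best percent identity against same-species
  records below `similarity_floor` (default 80%) → *review*. The floor is a
  package default (the threshold is not prescribed anywhere); 80% is far
  below normal within-species tRNA divergence (>95%) yet above what a
  mislabelled gene or shuffled contaminant attains. Single-record species
  cannot be checked and are left unflagged with a warning.

Disposition is a pure function of (sequence, reference, parameters), so QC
is idempotent; per-species before/after counts are reported.

## Alignment and coordinate mapping

Pairwise alignment is Needleman–Wunsch with match +1, mismatch −1, gap −2
and free end gaps (defaults; all configurable). The original workflow used
ClustalW, but for 70–75-nt near-identical genes the alignment is only ever
*read at reference columns*, so a progressive MSA is replaced by a
deterministic **reference-anchored star alignment**: each member is aligned
to the rCRS gene, insertion slots are merged (member insertions
left-aligned, padded with gaps), and `column_of_rcrs` maps every reference
position to its column. Determinism is guaranteed by a fixed traceback
preference — matching substitution, then gap in the member, then gap in the
reference, then mismatching substitution — which also resolves equal-score
optima to the identity-maximizing alignment. Gaps are then slid to the
3'-most position of any homopolymer run, the mtDNA convention for naming
indels (a G lost from the 3238/3239 GG run is the 3239 deletion).

Percent identity is 100 x identities / alignment length, reported to two
decimals; gap columns and Ns never count as identities. `N` is scored as a
mismatch everywhere. Identical member sequences are aligned once and share
rows, which keeps 400-record near-monomorphic panels cheap.

## Screening, aggregation, co-occurrence

A species x variant cell counts carriers of the alternate allele at the
mapped column. Rows with `N` or a gap at that column are excluded from the
denominator — unless the variant *is* a deletion, in which case the gap
character is the allele — and the exclusion count is reported. *Monomorphic*
means carriers = total > 0; a single-sequence species can be monomorphic.
Taxon aggregation pools carriers and totals over a lineage rank and reports
frequencies to three decimals; per-species percentage tables round half-up
to integers (so 57/391 prints as 15). Co-occurrence reports, per candidate
compensator, the 2x2 joint counts and the percentage of target carriers
that also carry the candidate.

## Pathogenicity rubric

Variants are classified neutral / possibly / probably / definitely
pathogenic by a point-based rubric in the style used in the mitochondrial
disease field: points for multiple independent reports, evolutionary
conservation, heteroplasmy, segregation with phenotype and a documented
biochemical defect, plus decisive weights for single muscle-fibre and
cybrid (trans-mitochondrial cell line) evidence. The published scheme's
exact point values are not restated in the sources this package draws on,
so the weights and class bands live in an editable YAML config
(`inst/extdata/yarham_rubric.yaml`) and the classification code is entirely
value-agnostic. The defaults score 2/2/2/2/3 for the reported criteria and
3/5 for the functional ones, with bands at 7 (possibly) and 11 (probably)
and a functional gate: a top-band score without single-fibre or cybrid
evidence is demoted to "probably". Under any non-negative weights the
classification is monotone: satisfying an extra criterion never lowers the
class. The packaged 32-entry Leu(UUR) catalogue with its evidence table
reproduces a 12/8/1/11 class split through this rubric.

## Cloverleaf template and compensation

Secondary structure is assessed against a fixed template rather than a
folding prediction: the screen only ever asks *which stem pair does this
position belong to and what pair class results*, for which thermodynamic
folding adds noise, not information. A template fixes the domain intervals
(acceptor, D, anticodon and T stems with their loops and the variable
region), the stem partner involution, and the tertiary interaction triples.

The packaged Leu(UUR) template places the D-stem at 10..13 paired with
27..24. This register was chosen because it is the only one that
simultaneously reproduces, on the reference sequence, the known properties
of this molecule's D-stem: two Watson–Crick pairs (10:27 G-C, 11:26 C-G),
one mismatch pair — i.e. two unpaired nucleotides — (12:25 A-C), and a G-U
wobble adjacent to the D-loop (13:24 G-T); under it, 3253T>C converts the
wobble to Watson–Crick, 3254C>T converts the mismatch to A-T, and 3256C>T
degrades a Watson–Crick pair to a wobble, exactly the substitutions observed
in canids and seals. Pair classes are `watson_crick` (A:T, G:C), `wobble`
(G:T), `mismatch`, and `unknown` for N/gap (excluded from tallies).

`assess_variant_structure()` applies a variant to a sequence and diffs the
pair annotations. With a background sequence (e.g. a carrier species'
consensus), the variant is applied to the background too and the impact is
*compensated* when every broken pair is held as Watson–Crick or wobble by
the background's other substitutions — or, for loop variants that break no
stem pair (like 3243A>G, which participates in the (8–14)–21 tertiary
triple), when the background substitutes another member of a touched triple
(the bears' 46 C>T against 3251A>G). Sequences with indels are anchored to
the template reference first; template positions falling in member gaps are
annotated `unknown` rather than shifted, so highly divergent molecules are
reported, not force-fitted.

## Median-joining network

Haplotypes are the distinct allele vectors over chosen rCRS positions, the
deletion state included as a fifth character, all characters weighted
equally. The network is built by computing the minimum spanning network
(Kruskal levels with tolerance `epsilon`, default 0), then repeatedly adding
majority-rule median vectors of linked triples (the inferred
unsampled/ancestral haplotypes) and rebuilding, until closure; unobserved
nodes of degree < 3 are pruned as superfluous. Two determinism choices: a
three-way tie in a median takes the first node's state, and nodes/edges are
emitted in a fixed order, so outputs are byte-stable. The final edge set is
unioned with the observed-haplotype minimum spanning network, guaranteeing
the epsilon=0 contract (the network contains the MSN) even when a median
chain would otherwise displace a direct alternative link.

Recurrence (the reading of a reticulation) is defined as: an identical
mutation — position plus unordered allele pair — labelling two or more edges
of some minimum-weight spanning tree of the network, unioned over all such
trees. This distinguishes true recurrence (the dog panel's 3239 deletion and
3243 A>G, each arising on two branches) from a position that merely carries
three states (3290, whose T>C and T>A are different single events) and from
alternative placements of one event (tie attachments). The node with the
largest count is annotated as the ancestral candidate under the frequency
heuristic; no rooting is claimed.

## Synthetic panels and what they show

`simulate_panel()` emits GenBank mini-genomes (~1.6 kb, six tRNA features
including both paralog pairs, one light-strand gene) rather than full
16.5-kb genomes: the pipeline consumes only annotated tRNA features, and
this keeps a 391-record panel generable in seconds. Injection is
deterministic — a variant configured at count k (or frequency f, k =
ceiling(f·n)) lands in exactly k records chosen by the seeded generator — so
recovered frequencies must equal injected frequencies *exactly*, which is
what the parameter-recovery tests assert; a Bernoulli mode exists behind the
`bernoulli` flag for stress testing. Species can instead be specified as
whole haplotype groups; the shipped dog preset encodes the six published
dog haplogroups (328/3/2/1/2/55 over characters 3230/3239/3243/3290) on a
canid background carrying 3253C and 3254T. The second preset is a
desk-scale 275-record, 10-species, 8-order panel; printed per-order count
tables are separately packaged as fixtures for the aggregation worked
examples.

What passing on synthetic panels does *not* show: real GenBank records have
richer annotation pathologies (nonstandard product strings, fuzzy
coordinates `<`/`>` beyond simple stripping, multi-interval genes across the
origin of the circular genome), sequencing error is not independent of
lineage, and real within-species diversity is coalescent-shaped rather than
a fixed haplotype mixture. The generator validates the machinery —
coordinate mapping, exact counting, defect handling — not the biology of any
particular species.

## Numerical conventions and degenerate inputs

- Rounding is half-up (away from zero) everywhere a table is printed:
  integer percentages, 3-decimal frequencies, 2-decimal identities.
- Alignment of an empty sequence, a zero-length alignment, out-of-interval
  coordinate lookups, a variant whose reference allele contradicts the
  sequence, and contradictory injections are all hard errors naming the
  offending item.
- Empty QC input, species with one record, records with no tRNA features,
  and species whose records all fail QC degrade to warnings plus empty
  outputs, so one bad species never aborts a run.
- Test-suite problem sizes: the full dog preset (391 records) and the
  multi-order preset (275 records) run in the parameter-recovery tests;
  property suites use 1,000 random gapped alignments for the coordinate
  round-trip and exhaustive alignment enumeration up to length 6.

## Known limitations

- Stems templates ship for Leu(UUR) only; other genes (and non-mammalian
  D-stem registers, which differ in sharks, eels and amphibians) must be
  supplied as user template files.
- The star alignment assumes members are alignable to the reference
  end-to-end; a gene fused with flanking sequence would need trimming first.
- Median-joining is exact but exhaustive in places (spanning-tree
  enumeration for recurrence detection); it is intended for the small
  within-species networks of this analysis, not thousand-haplotype
  population graphs.
- The rubric classifies from an evidence table; it does not extract evidence
  from the literature.
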