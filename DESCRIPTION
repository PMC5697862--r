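Package: mttrnascreen
Title: Cross-Species Screening of Disease-Associated Mitochondrial tRNA Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether human disease-associated mitochondrial
    tRNA variants (such as the MELAS mutation m.3243A>G in mt-tRNA-Leu(UUR))
    segregate as normal population variants in other chordate species, and
    whether compensatory substitutions in the tRNA cloverleaf accompany them.
    Extracts annotated mt-tRNA genes from GenBank flat files with
    disambiguation of the duplicated Leu/Ser paralogs, applies sequence
    quality control, builds reference-anchored alignments with gap-aware rCRS
    coordinate mapping, screens a variant catalogue for carrier frequencies
    and monomorphism across species and taxa, classifies variants with a
    configurable point-based pathogenicity rubric, evaluates variant impact on
    template-based cloverleaf secondary structure including compensatory
    changes, and builds median-joining haplotype networks with recurrence
    detection. A synthetic GenBank panel generator with a known truth table
    makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
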