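# Cloverleaf template for human mt-tRNA-Leu(UUR) (75 nt, molecule
# coordinates). The D-stem register pairs 10..13 with 27..24; on the
# reference molecule this gives two Watson-Crick pairs (10:27 G-C,
# 11:26 C-G), one mismatch pair (12:25 A-C, i.e. two unpaired nucleotides)
# and a G-U wobble adjacent to the D-loop (13:24 G-T). Positions 8, 9 and
# 68 are connector nucleotides outside the named domains.
gene: tRNA-Leu(UUR)
reference: GTTAAGATGGCAGAGCCCGGTAATCGCATAAAACTTAAAACTTTACAGTCAGAGGTTCAATTCCTCTTCTTAACA
regions:
  acc-stem: [[1, 7], [69, 75]]
  d-stem: [[10, 13], [24, 27]]
  d-loop: [[14, 23]]
  ac-stem: [[28, 32], [40, 44]]
  ac-loop: [[33, 39]]
  variable: [[45, 47]]
  t-stem: [[48, 52], [63, 67]]
  t-loop: [[53, 62]]
pairs:
  - [1, 75]
  - [2, 74]
  - [3, 73]
  - [4, 72]
  - [5, 71]
  - [6, 70]
  - [7, 69]
  - [10, 27]
  - [11, 26]
  - [12, 25]
  - [13, 24]
  - [28, 44]
  - [29, 43]
  - [30, 42]
  - [31, 41]
  - [32, 40]
  - [48, 67]
  - [49, 66]
  - [50, 65]
  - [51, 64]
  - [52, 63]
tertiary:
  - [8, 14, 21]
  - [13, 22, 46]
  - [10, 25, 45]
  - [26, 44]
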