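# Dog panel preset: 391 synthetic records of Canis lupus familiaris whose
# Leu(UUR) haplotype groups reproduce the printed dog haplotype table
# (six groups over characters 3230/3239/3243/3290; 57 records carry 3243G).
# The species background carries the canid divergences from the human
# reference: the D-stem compensators 3253C and 3254T plus four further
# neutral background substitutions.
seed: 20170101
species:
  - name: Canis lupus familiaris
    lineage: [Eukaryota, Metazoa, Chordata, Mammalia, Carnivora, Canidae]
    n_records: 391
    background: {"3253": C, "3254": T, "3234": G, "3300": C, "3276": G, "3286": C}
    haplotypes:
      positions: [3230, 3239, 3243, 3290]
      groups:
        - {alleles: [G, G, A, T], count: 328}
        - {alleles: [G, "-", A, T], count: 3}
        - {alleles: [G, G, A, C], count: 2}
        - {alleles: ["-", G, A, A], count: 1}
        - {alleles: [G, "-", G, T], count: 2}
        - {alleles: [G, G, G, T], count: 55}
defects: {excess_n: 0, length_outlier: 0, paralog_mislabel: 0}
noise_rate: 0
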