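# Multi-order panel preset (scaled to desk size): ten synthetic species
# across eight orders, exercising monomorphic backgrounds (including the
# bear-like 3251G with its tertiary-triple compensator 3275C>T, molecule
# position 46), polymorphic injections (dog-like 3243G, macaque-like 3253C), a
# single-sequence species, and the near-universal 3254T background.
seed: 20170102
species:
  - name: Elephas syntheticus
    lineage: [Eukaryota, Metazoa, Chordata, Mammalia, Proboscidea, Elephantidae]
    n_records: 30
    background: {"3253": C, "3254": T}
  - name: Ursus syntheticus
    lineage: [Eukaryota, Metazoa, Chordata, Mammalia, Carnivora, Ursidae]
    n_records: 30
    background: {"3251": G, "3275": T, "3254": T}
    injections:
      - {position: 3244, alt: A, count: 2}
  - name: Canis syntheticus
    lineage: [Eukaryota, Metazoa, Chordata, Mammalia, Carnivora, Canidae]
    n_records: 34
    background: {"3253": C, "3254": T}
    injections:
      - {position: 3243, alt: G, count: 5}
  - name: Macaca synthetica
    lineage: [Eukaryota, Metazoa, Chordata, Mammalia, Primates, Cercopithecidae]
    n_records: 30
    background: {"3254": T}
    injections:
      - {position: 3253, alt: C, count: 8}
  - name: Mus syntheticus
    lineage: [Eukaryota, Metazoa, Chordata, Mammalia, Rodentia, Muridae]
    n_records: 30
    background: {"3271": C, "3254": T, "3303": T}
  - name: Sus syntheticus
    lineage: [Eukaryota, Metazoa, Chordata, Mammalia, Cetartiodactyla, Suidae]
    n_records: 30
    background: {"3254": T}
    injections:
      - {position: 3249, alt: A, count: 1}
  - name: Clupea synthetica
    lineage: [Eukaryota, Metazoa, Chordata, Actinopterygii, Neoteleostei, Clupeidae]
    n_records: 30
    background: {"3273": C, "3302": G, "3254": T}
  - name: Anguilla synthetica
    lineage: [Eukaryota, Metazoa, Chordata, Actinopterygii, Anguilliformes, Anguillidae]
    n_records: 30
    background: {"3264": C, "3271": C, "3290": C, "3254": T}
  - name: Xenagama synthetica
    lineage: [Eukaryota, Metazoa, Chordata, Reptilia, Squamata, Agamidae]
    n_records: 1
    background: {"3243": G, "3254": T}
  - name: Pteropus syntheticus
    lineage: [Eukaryota, Metazoa, Chordata, Mammalia, Chiroptera, Pteropodidae]
    n_records: 30
    background: {"3254": T}
defects: {excess_n: 0, length_outlier: 0, paralog_mislabel: 0}
noise_rate: 0
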