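>SYNAMPH01|Scolecomorphus-like synthetic|tRNA-Leu(UUR)
GCCAGGATGGCAAGGCTCAGTAATTGCACAGAATTTGAAATTCTACAGTTAGAGATTTAATTCTTTTTCTCAACA
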