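# Point-based mt-tRNA variant pathogenicity rubric (transcribed weights;
# the classification code is value-agnostic and reads everything from here).
# A variant scores the 'independent_reports' points once it has been
# reported in at least multi_report_threshold independent studies. Scores
# below the 'possibly' band are neutral. With functional_gate on, a score in
# the 'probably' band is promoted to definitely only when single-fibre or
# cybrid/in-vitro evidence is present.
multi_report_threshold: 2
weights:
  independent_reports: 2
  evolutionary_conservation: 2
  heteroplasmy: 2
  segregation_with_phenotype: 2
  biochemical_defect: 3
  single_fibre_evidence: 3
  cybrid_or_in_vitro_evidence: 5
class_bands:
  possibly: 7
  probably: 11
functional_gate: true
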