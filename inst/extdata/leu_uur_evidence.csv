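position,ref,alt,independent_reports,evolutionary_conservation,heteroplasmy,segregation_with_phenotype,biochemical_defect,single_fibre_evidence,cybrid_or_in_vitro_evidence
3234,A,G,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3236,A,G,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3242,G,A,6,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
3243,A,G,6,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
3244,G,A,6,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
3249,G,A,3,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
3250,T,C,3,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
3251,A,G,3,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
3252,A,G,6,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
3253,T,C,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3254,C,T,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3255,G,A,3,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
3256,C,T,6,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
3258,T,C,6,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
3260,A,G,6,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
3262,A,G,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3264,T,C,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3265,T,C,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3271,T,C,6,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
3273,T,C,6,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
3274,A,G,3,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
3275,C,A,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3277,G,A,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3280,A,G,6,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
3282,A,G,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3288,A,G,3,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
3289,A,G,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3290,T,C,1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3291,T,C,3,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
3296,T,C,3,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
3302,A,G,6,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
3303,C,T,4,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
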