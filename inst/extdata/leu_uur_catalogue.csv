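# mt-tRNA-Leu(UUR) disease-associated variant catalogue (rCRS coordinates,
# heavy-strand alleles; "-" = deletion). The screened positions discussed in
# the package documentation carry their literature classifications; the
# remaining rows are synthetic-but-realistic entries completing a catalogue
# of 32 with a 12 neutral / 8 possibly / 1 probably / 11 definitely split.
# tertiary = long-range interaction partners in molecule coordinates.
position,ref,alt,gene,region,class,tertiary
3234,A,G,tRNA-Leu(UUR),acc-stem,neutral,
3236,A,G,tRNA-Leu(UUR),acc-stem,neutral,
3242,G,A,tRNA-Leu(UUR),d-stem,definitely,
3243,A,G,tRNA-Leu(UUR),d-loop,definitely,(8-14)-21
3244,G,A,tRNA-Leu(UUR),d-loop,definitely,
3249,G,A,tRNA-Leu(UUR),d-loop,possibly,
3250,T,C,tRNA-Leu(UUR),d-loop,possibly,(8-14)-21
3251,A,G,tRNA-Leu(UUR),d-loop,possibly,(13-22)-46
3252,A,G,tRNA-Leu(UUR),d-loop,definitely,
3253,T,C,tRNA-Leu(UUR),d-stem,neutral,
3254,C,T,tRNA-Leu(UUR),d-stem,neutral,(25-10)-45
3255,G,A,tRNA-Leu(UUR),d-stem,possibly,
3256,C,T,tRNA-Leu(UUR),d-stem,definitely,
3258,T,C,tRNA-Leu(UUR),ac-stem,definitely,
3260,A,G,tRNA-Leu(UUR),ac-stem,definitely,
3262,A,G,tRNA-Leu(UUR),ac-loop,neutral,
3264,T,C,tRNA-Leu(UUR),ac-loop,neutral,
3265,T,C,tRNA-Leu(UUR),ac-loop,neutral,
3271,T,C,tRNA-Leu(UUR),ac-stem,definitely,
3273,T,C,tRNA-Leu(UUR),ac-stem,definitely,26-44
3274,A,G,tRNA-Leu(UUR),variable,possibly,
3275,C,A,tRNA-Leu(UUR),variable,neutral,(13-22)-46
3277,G,A,tRNA-Leu(UUR),t-stem,neutral,
3280,A,G,tRNA-Leu(UUR),t-stem,definitely,
3282,A,G,tRNA-Leu(UUR),t-loop,neutral,
3288,A,G,tRNA-Leu(UUR),t-loop,possibly,
3289,A,G,tRNA-Leu(UUR),t-loop,neutral,
3290,T,C,tRNA-Leu(UUR),t-loop,neutral,
3291,T,C,tRNA-Leu(UUR),t-loop,possibly,
3296,T,C,tRNA-Leu(UUR),t-stem,possibly,
3302,A,G,tRNA-Leu(UUR),acc-stem,definitely,
3303,C,T,tRNA-Leu(UUR),acc-stem,probably,
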