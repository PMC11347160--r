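# CFD PAM factors for SpCas9 (Doench et al. 2016); key = bases 2-3 of the NGG PAM.
pam,factor
AA,0.0
AC,0.0
AG,0.25925926
AT,0.0
CA,0.0
CC,0.0
CG,0.10714286
CT,0.0
GA,0.06944444
GC,0.02222222
GG,1.0
GT,0.01612903
TA,0.0
TC,0.0
TG,0.03896104
TT,0.0
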