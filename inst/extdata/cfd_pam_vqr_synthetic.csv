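# SYNTHETIC model PAM factors for SpCas9-VQR (canonical NGA); not measured data.
pam,factor
AA,0.0
AC,0.0
AG,0.05
AT,0.0
CA,0.0
CC,0.0
CG,0.0
CT,0.0
GA,1.0
GC,0.02
GG,0.3
GT,0.02
TA,0.0
TC,0.0
TG,0.01
TT,0.0
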