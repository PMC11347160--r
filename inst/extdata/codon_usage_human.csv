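# Human codon usage (standard published per-thousand frequencies, normalised to fractions).
codon,fraction
TTT,0.017596
TTC,0.020296
TTA,0.007698
TTG,0.012897
CTT,0.013197
CTC,0.019596
CTA,0.007199
CTG,0.039592
ATT,0.015997
ATC,0.020796
ATA,0.007499
ATG,0.021996
GTT,0.010998
GTC,0.014497
GTA,0.007099
GTG,0.028094
TCT,0.015197
TCC,0.017696
TCA,0.012198
TCG,0.004399
CCT,0.017497
CCC,0.019796
CCA,0.016897
CCG,0.006899
ACT,0.013097
ACC,0.018896
ACA,0.015097
ACG,0.006099
GCT,0.018396
GCC,0.027694
GCA,0.015797
GCG,0.007399
TAT,0.012198
TAC,0.015297
TAA,0.001000
TAG,0.000800
CAT,0.010898
CAC,0.015097
CAA,0.012298
CAG,0.034193
AAT,0.016997
AAC,0.019096
AAA,0.024395
AAG,0.031894
GAT,0.021796
GAC,0.025095
GAA,0.028994
GAG,0.039592
TGT,0.010598
TGC,0.012597
TGA,0.001600
TGG,0.013197
CGT,0.004499
CGC,0.010398
CGA,0.006199
CGG,0.011398
AGT,0.012098
AGC,0.019496
AGA,0.012198
AGG,0.011998
GGT,0.010798
GGC,0.022196
GGA,0.016497
GGG,0.016497
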