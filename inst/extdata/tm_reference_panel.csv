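# Reference primer panel; tm_oracle computed once with an independent
# nearest-neighbour implementation (Biopython MeltingTemp.Tm_NN, DNA_NN3,
# saltcorr=5, Na=50 mM, Mg=1.5 mM, dNTPs=0.6 mM, dnac1=dnac2=25 nM).
sequence,tm_oracle
ACGTTAGCATCGGATCCA,55.6793
TGCATGCATGCATGCATG,57.5653
GATTACAGATTACAGATTACA,48.0759
CGCGCGATATCGCGCTAGCT,65.7538
ATATATATATATGCGCGCGC,53.6283
GGCCTTAAGGCCTTAAGGCC,60.7557
TTGACCTAGATCGGAAGAGCACACG,64.3174
AACCGGTTAACCGGTTAACCGGT,64.5080
CTGATCGTAGCTAGCTAGCA,56.3526
GTGTGTGAGAGACACACTCT,56.8330
AAGGTTCCAAGGTTCCAAGG,57.6182
CCATGGTACCATGGTACCAT,56.6540
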