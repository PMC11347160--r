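# SYNTHETIC model PAM factors for enAsCas12a (canonical TTTV, 5' side); not measured data.
pam,factor
AAAA,0.0
AAAC,0.0
AAAG,0.0
AAAT,0.0
AACA,0.0
AACC,0.0
AACG,0.0
AACT,0.0
AAGA,0.0
AAGC,0.0
AAGG,0.0
AAGT,0.0
AATA,0.0
AATC,0.0
AATG,0.0
AATT,0.0
ACAA,0.0
ACAC,0.0
ACAG,0.0
ACAT,0.0
ACCA,0.0
ACCC,0.0
ACCG,0.0
ACCT,0.0
ACGA,0.0
ACGC,0.0
ACGG,0.0
ACGT,0.0
ACTA,0.0
ACTC,0.0
ACTG,0.0
ACTT,0.0
AGAA,0.0
AGAC,0.0
AGAG,0.0
AGAT,0.0
AGCA,0.0
AGCC,0.0
AGCG,0.0
AGCT,0.0
AGGA,0.0
AGGC,0.0
AGGG,0.0
AGGT,0.0
AGTA,0.0
AGTC,0.0
AGTG,0.0
AGTT,0.0
ATAA,0.0
ATAC,0.0
ATAG,0.0
ATAT,0.0
ATCA,0.0
ATCC,0.0
ATCG,0.0
ATCT,0.0
ATGA,0.0
ATGC,0.0
ATGG,0.0
ATGT,0.0
ATTA,0.02
ATTC,0.02
ATTG,0.02
ATTT,0.0
CAAA,0.0
CAAC,0.0
CAAG,0.0
CAAT,0.0
CACA,0.0
CACC,0.0
CACG,0.0
CACT,0.0
CAGA,0.0
CAGC,0.0
CAGG,0.0
CAGT,0.0
CATA,0.0
CATC,0.0
CATG,0.0
CATT,0.0
CCAA,0.0
CCAC,0.0
CCAG,0.0
CCAT,0.0
CCCA,0.0
CCCC,0.0
CCCG,0.0
CCCT,0.0
CCGA,0.0
CCGC,0.0
CCGG,0.0
CCGT,0.0
CCTA,0.0
CCTC,0.0
CCTG,0.0
CCTT,0.0
CGAA,0.0
CGAC,0.0
CGAG,0.0
CGAT,0.0
CGCA,0.0
CGCC,0.0
CGCG,0.0
CGCT,0.0
CGGA,0.0
CGGC,0.0
CGGG,0.0
CGGT,0.0
CGTA,0.0
CGTC,0.0
CGTG,0.0
CGTT,0.0
CTAA,0.0
CTAC,0.0
CTAG,0.0
CTAT,0.0
CTCA,0.0
CTCC,0.0
CTCG,0.0
CTCT,0.0
CTGA,0.0
CTGC,0.0
CTGG,0.0
CTGT,0.0
CTTA,0.02
CTTC,0.02
CTTG,0.02
CTTT,0.0
GAAA,0.0
GAAC,0.0
GAAG,0.0
GAAT,0.0
GACA,0.0
GACC,0.0
GACG,0.0
GACT,0.0
GAGA,0.0
GAGC,0.0
GAGG,0.0
GAGT,0.0
GATA,0.0
GATC,0.0
GATG,0.0
GATT,0.0
GCAA,0.0
GCAC,0.0
GCAG,0.0
GCAT,0.0
GCCA,0.0
GCCC,0.0
GCCG,0.0
GCCT,0.0
GCGA,0.0
GCGC,0.0
GCGG,0.0
GCGT,0.0
GCTA,0.0
GCTC,0.0
GCTG,0.0
GCTT,0.0
GGAA,0.0
GGAC,0.0
GGAG,0.0
GGAT,0.0
GGCA,0.0
GGCC,0.0
GGCG,0.0
GGCT,0.0
GGGA,0.0
GGGC,0.0
GGGG,0.0
GGGT,0.0
GGTA,0.0
GGTC,0.0
GGTG,0.0
GGTT,0.0
GTAA,0.0
GTAC,0.0
GTAG,0.0
GTAT,0.0
GTCA,0.0
GTCC,0.0
GTCG,0.0
GTCT,0.0
GTGA,0.0
GTGC,0.0
GTGG,0.0
GTGT,0.0
GTTA,0.02
GTTC,0.02
GTTG,0.02
GTTT,0.0
TAAA,0.0
TAAC,0.0
TAAG,0.0
TAAT,0.0
TACA,0.0
TACC,0.0
TACG,0.0
TACT,0.0
TAGA,0.0
TAGC,0.0
TAGG,0.0
TAGT,0.0
TATA,0.02
TATC,0.02
TATG,0.02
TATT,0.0
TCAA,0.0
TCAC,0.0
TCAG,0.0
TCAT,0.0
TCCA,0.0
TCCC,0.0
TCCG,0.0
TCCT,0.0
TCGA,0.0
TCGC,0.0
TCGG,0.0
TCGT,0.0
TCTA,0.02
TCTC,0.02
TCTG,0.02
TCTT,0.0
TGAA,0.0
TGAC,0.0
TGAG,0.0
TGAT,0.0
TGCA,0.0
TGCC,0.0
TGCG,0.0
TGCT,0.0
TGGA,0.0
TGGC,0.0
TGGG,0.0
TGGT,0.0
TGTA,0.02
TGTC,0.02
TGTG,0.02
TGTT,0.0
TTAA,0.02
TTAC,0.02
TTAG,0.02
TTAT,0.0
TTCA,0.02
TTCC,0.02
TTCG,0.02
TTCT,0.0
TTGA,0.02
TTGC,0.02
TTGG,0.02
TTGT,0.0
TTTA,1.0
TTTC,1.0
TTTG,1.0
TTTT,0.15
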