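# Unified nearest-neighbour DNA duplex parameters (SantaLucia & Hicks 2004).
# dH kcal/mol, dS cal/(mol K). Keys: XY/ZW = top-strand dinucleotide / bottom strand.
key,dH,dS
AA/TT,-7.9,-22.2
AT/TA,-7.2,-20.4
CA/GT,-8.5,-22.7
CG/GC,-10.6,-27.2
CT/GA,-7.8,-21.0
GA/CT,-8.2,-22.2
GC/CG,-9.8,-24.4
GG/CC,-8.0,-19.9
GT/CA,-8.4,-22.4
TA/AT,-7.2,-21.3
init,0,0
init_5T/A,0,0
init_A/T,2.3,4.1
init_G/C,0.1,-2.8
init_allA/T,0,0
init_oneG/C,0,0
sym,0,-1.4
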