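# synthetic biomolecular toy particle set
[Particle description]
# name mass charge volume color
H2O 18 0 30 blue
BB 56 0 60 grey
SC 45 0 55 green
SCQ 45 0 55 red

[Particle interactions]
pair 298 310
H2O_H2O 25 25.5
BB_BB 25 25.4
SC_SC 25 25.3
SCQ_SCQ 25 25.3
H2O_BB 28 28.4
H2O_SC 30 30.2
H2O_SCQ 22 22.2
BB_SC 26 26.1
BB_SCQ 27 27.1
SC_SCQ 27 27.2

[Amino acids]
# one three spices backboneIndex pKa chargedVariant
G Gly BB 1 - -
A Ala BB-SC 1 - -
K Lys BB-SC 1 10.5 charged=BB-SCQ[+]
E Glu BB-SC 1 4.1 charged=BB-SCQ[-]
C Cys BB-SC 1 8.3 charged=BB-SCQ[-]
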