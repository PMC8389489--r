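name,x,y
Fp1,-0.4,0.8
Fp2,0.4,0.8
AF3,-0.2,0.6
AF4,0.2,0.6
F7,-0.8,0.4
F3,-0.4,0.4
Fz,0,0.4
F4,0.4,0.4
F8,0.8,0.4
FC5,-0.6,0.2
FC1,-0.2,0.2
FC2,0.2,0.2
FC6,0.6,0.2
T7,-0.8,0
C3,-0.4,0
Cz,0,0
C4,0.4,0
T8,0.8,0
CP5,-0.6,-0.2
CP1,-0.2,-0.2
CP2,0.2,-0.2
CP6,0.6,-0.2
P7,-0.8,-0.4
P3,-0.4,-0.4
Pz,0,-0.4
P4,0.4,-0.4
P8,0.8,-0.4
PO3,-0.2,-0.6
PO4,0.2,-0.6
O1,-0.4,-0.8
Oz,0,-0.8
O2,0.4,-0.8
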