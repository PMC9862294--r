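label,area_id
Fp2,1
AF4,1
AF8,1
F2,1
F4,1
F6,1
F8,1
F10,1
Fp1,2
AF3,2
AF7,2
F1,2
F3,2
F5,2
F7,2
F9,2
Fpz,3
Fz,3
FC2,4
FC4,4
FC6,4
C2,4
C4,4
C6,4
T8,4
CP2,4
CP4,4
CP6,4
TP8,4
P2,4
P4,4
P6,4
P8,4
FC1,5
FC3,5
FC5,5
C1,5
C3,5
C5,5
T7,5
CP1,5
CP3,5
CP5,5
TP7,5
P1,5
P3,5
P5,5
P7,5
FCz,6
Cz,6
CPz,6
Pz,6
PO4,7
PO8,7
O2,7
PO3,8
PO7,8
O1,8
POz,9
Oz,9
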