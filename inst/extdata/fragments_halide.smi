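*F
*Cl
*Br
*I
*C(F)(F)F
*OC
*O
*N
*C#N
*[N+](=O)[O-]
*OC(F)(F)F
*SC
*OCC
*C(=O)OC
*NC
*OC(C)C
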