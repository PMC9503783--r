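*c1ccccc1
*c1ccc(C)cc1
*c1ccc(F)cc1
*c1ccc(Cl)cc1
*c1ccc(OC)cc1
*c1ccc(C(F)(F)F)cc1
*c1ccccc1C
*c1ccccc1F
*c1ccccc1Cl
*c1cccc(C)c1
*c1cccc(F)c1
*c1cccc(Cl)c1
*c1ccc(CC)cc1
*c1ccc(O)cc1
*c1ccc(N)cc1
*Cc1ccccc1
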