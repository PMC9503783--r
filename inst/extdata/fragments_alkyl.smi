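*C
*CC
*CCC
*C(C)C
*CCCC
*C(C)(C)C
*CC(C)C
*CCCCC
*C1CC1
*C1CCC1
*C1CCCC1
*C1CCCCC1
*CC=C
*CC#C
*CCO
*CCOC
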