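*c1ccncc1
*c1cccnc1
*c1ccccn1
*c1ccco1
*c1cccs1
*c1cc[nH]c1
*c1cncnc1
*c1ccnnc1
*c1cnccn1
*c1csc(C)n1
*c1occc1C
*c1scnc1C
*Cc1ccncc1
*Cc1ccco1
*c1cnc[nH]1
*c1ncc[nH]1
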