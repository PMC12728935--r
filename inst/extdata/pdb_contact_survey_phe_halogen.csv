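group,contacts,interactions
Cl,7667,806
Br,1874,198
I,633,110
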