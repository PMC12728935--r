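group,contacts,interactions
histidine,3597,661
phenylalanine,10174,1114
tryptophan,2855,384
tyrosine,6910,1152
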