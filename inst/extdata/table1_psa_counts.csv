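category,cases,controls
psa_ge_3,49,16
psa_lt_3,97,256
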