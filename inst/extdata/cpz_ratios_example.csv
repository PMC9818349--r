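drug,multiplier,source
chlorpromazine,1.0,definition
example_drug_a,2.0,illustrative example only
example_drug_b,0.5,illustrative example only
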