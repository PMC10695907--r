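animal_id,bioptome,n_manoeuvres,n_biopsies,major_complication
P1,B1,6,6,FALSE
P2,B1,8,7,FALSE
P3,B1,8,7,FALSE
P4,B2,10,9,FALSE
P5,B2,11,9,FALSE
P6,B2,8,7,FALSE
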