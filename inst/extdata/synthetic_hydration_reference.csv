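molecule_id,dg_exp_kjmol
S1,-11.0
S2,-6.2
S3,-8.9
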