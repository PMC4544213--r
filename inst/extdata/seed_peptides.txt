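# Seed-proteome tryptic peptide signatures matching the beta-type VPE
# tandem duplicates (one peptide per line; see read_peptides()).
GIIINHPQGEDVYAGVPK
HQADVCHAYQLLLK
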