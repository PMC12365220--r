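# Restriction sites commonly excluded from synthesized inserts, plus a
# synthetic stand-in for a viral inverted-terminal-repeat fragment.
EcoRI	GAATTC
BamHI	GGATCC
HindIII	AAGCTT
NheI	GCTAGC
KpnI	GGTACC
NcoI	CCATGG
itr_like_synthetic	GCGCTCGCTCGCTCACTGAGG
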