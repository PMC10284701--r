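# Synthetic T-stem base-pair free-energy table (kcal/mol) for eEF1A
# binding, modelled on the additive per-pair contributions measured for
# the bacterial EF-Tu:tRNA-Phe complex. Values are RELATIVE to the
# serine-scaffold wild-type pair at each position class (which scores 0
# by construction); negative = stabilized elongation-factor binding.
# These are illustrative stand-in numbers, not the published
# measurements; edit this file to use a measured table.
position_class	nt5	nt3	ddg
49-65	G	C	0.0
49-65	C	G	-0.4
49-65	A	U	0.9
49-65	U	A	1.1
49-65	G	U	1.6
50-64	C	G	0.0
50-64	G	C	-0.1
50-64	A	U	1.0
50-64	U	A	1.2
50-64	G	U	1.4
51-63	G	C	0.0
51-63	C	G	-0.2
51-63	U	A	0.7
51-63	A	U	0.8
51-63	G	U	1.3
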