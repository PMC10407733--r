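# Identity-element catalog for the phosphoserine orthogonal pair in
# E. coli. source = characterized entries vs literature-supplemented
# ones; essential structural elements act as a veto in host screening.
aars	kind	pos5	pos3	required	structural_feature	threshold	essential	flag_threshold	source
GlyRS	base_pair	1	72	G:C	NA	NA	FALSE	3	characterized
GlyRS	base_pair	2	71	C:G	NA	NA	FALSE	3	characterized
GlyRS	base	73	NA	U	NA	NA	FALSE	3	characterized
ThrRS	base_pair	1	72	G:C	NA	NA	FALSE	3	characterized
ThrRS	base_pair	2	71	C:G	NA	NA	FALSE	3	characterized
ThrRS	base	73	NA	U	NA	NA	FALSE	3	characterized
SerRS	structural	NA	NA	NA	extended_variable_loop	10	TRUE	3	characterized
SerRS	base_pair	2	71	G:C	NA	NA	FALSE	3	literature
SerRS	base	73	NA	G	NA	NA	FALSE	3	literature
pSerRS	base_pair	1	72	G:C	NA	NA	TRUE	2	characterized
pSerRS	base	73	NA	U	NA	NA	TRUE	2	characterized
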