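element	isotope	mass	abundance
H	1H	1.00782503207	0.999885
H	2H	2.01410177785	0.000115
C	12C	12.0	0.9893
C	13C	13.0033548378	0.0107
N	14N	14.0030740048	0.99636
N	15N	15.0001088982	0.00364
O	16O	15.9949146196	0.99757
O	17O	16.9991317012	0.00038
O	18O	17.9991610070	0.00205
P	31P	30.9737616320	1.0
S	32S	31.9720710015	0.9499
S	33S	32.9714587615	0.0075
S	34S	33.9678669012	0.0425
S	36S	35.9670807620	0.0001
F	19F	18.9984032200	1.0
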