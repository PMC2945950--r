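# synthetic demo pathway (12 nodes, all edge types)
LIG	RTK	directed	
RTK	ADAP	phospho_plus	
SCAF	ADAP	directed	
ADAP	GTP	directed	
KIN1	GTP	inhibition	
GTP	MAPK	directed	
KIN2	MAPK	phospho_plus	
MAPK	TF1	directed	
MAPK	TF2	directed	
PHOS	RTK	phospho_minus	
TF1	OUT	undirected	forward
TF2	OUT	directed	
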