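id	sequence	n_a	n_t	n_c	n_g	calculated_score	tolerance_score
nc01	TCCactaaccaatatAAC	8	4	6	0	89	0.2
nc02	TAActaacttaactcAAC	8	5	5	0	89	0.2
nc03	CACaatctaactattAAC	8	5	5	0	89	0.5
nc04	AAAtctataataaccacCAC	10	4	6	0	82	0
nc05	CACaactattaaataccAAC	10	4	6	0	82	0.7
nc06	TACcatacaataactttAAC	9	6	5	0	81	0
nc07	CTAatattataaccatcAAC	9	6	5	0	81	0.2
nc08	TACtcaaatataacaccAAC	10	4	6	0	82	0.2
nc09	CAACcaacaatactttAAAC	10	4	6	0	82	0.2
nc10	CAAAtcatccatctatAAAC	9	5	6	0	81	0
nc11	CAAActtatatctttcAAAC	8	7	5	0	80	0
nc12	CTAAatccttaatatcAAAC	9	6	5	0	81	0
nc13	CcAAAtcttataataACtAC	9	6	5	0	81	0
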