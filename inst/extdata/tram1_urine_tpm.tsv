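accession	transcript_id	type	exons	length	tsl	biotype	group	tpm
ENST00000520700	TRAM1-203	linear	6	542	5	processed-transcript	HR	1.63
ENST00000520700	TRAM1-203	linear	6	542	5	processed-transcript	C	20.12
ENST00000521425	TRAM1-205	linear	11	3394	2	protein-coding	HR	5.13
ENST00000521425	TRAM1-205	linear	11	3394	2	protein-coding	C	8.14
ENST00000262213	TRAM1-201	linear	11	3056	1	protein-coding	HR	6.08
ENST00000262213	TRAM1-201	linear	11	3056	1	protein-coding	C	8.43
ENST00000521049	TRAM1-204	linear	7	872	5	processed-transcript	HR	3.70
ENST00000521049	TRAM1-204	linear	7	872	5	processed-transcript	C	2.81
ENST00000518678	TRAM1-202	linear	5	535	4	protein-coding	HR	4.34
ENST00000518678	TRAM1-202	linear	5	535	4	protein-coding	C	3.04
hsa_circ_0084758	circTRAM1-58	circular	2	176	NA	NA	HR	0.66
hsa_circ_0084758	circTRAM1-58	circular	2	176	NA	NA	C	41.33
hsa_circ_0084756	circTRAM1-56	circular	4	383	NA	NA	HR	0.81
hsa_circ_0084756	circTRAM1-56	circular	4	383	NA	NA	C	21.56
hsa_circ_0084757	circTRAM1-57	circular	5	447	NA	NA	HR	0.98
hsa_circ_0084757	circTRAM1-57	circular	5	447	NA	NA	C	18.51
hsa_circ_0084759	circTRAM1-59	circular	5	422	NA	NA	HR	3.08
hsa_circ_0084759	circTRAM1-59	circular	5	422	NA	NA	C	20.04
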