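transcript	group	value
TRAM1	HR	4.28
TRAM1	C	12.23
TRAM1	ECV-304	3287.14
TRAM1	RT-4	12809.89
circTRAM1-56	HR	0.81
circTRAM1-56	C	21.56
circTRAM1-56	ECV-304	9.96
circTRAM1-56	RT-4	17.56
circTRAM1-57	HR	0.98
circTRAM1-57	C	18.51
circTRAM1-57	ECV-304	87.81
circTRAM1-57	RT-4	187.96
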