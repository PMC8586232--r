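transcript	replicate	copies_no_rnase_r	copies_rnase_r
TRAM1	1	66353.49	223.56
circTRAM1-56	1	16.18	86.13
circTRAM1-56	2	13.66	74.90
circTRAM1-57	1	100.04	144.75
circTRAM1-57	2	94.22	105.11
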