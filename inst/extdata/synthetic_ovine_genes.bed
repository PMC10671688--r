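1	131000000	131400000	TIAM1
2	219000000	219190000	BMPR2
3	182500000	182750000	MYBPC1
4	42500000	42980000	CACNA2D1
6	34000000	34440000	BMPR1B
6	78400000	78500000	CLOCK
13	2000000	2260000	TASP1
13	50900000	51210000	BMP2
17	62000000	62150000	KDM2B
23	42500000	42640000	MYOM1
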