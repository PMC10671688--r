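##gff-version 3
# Synthetic gene intervals for examples and tests: gene symbols are real
# ovine candidate genes but the coordinates are invented (placed inside the
# ROH island spans used in the package documentation). Not a genome build.
1	rohscan	gene	131000001	131400000	.	+	.	ID=gene1;Name=TIAM1
2	rohscan	gene	219000001	219190000	.	+	.	ID=gene2;Name=BMPR2
3	rohscan	gene	182500001	182750000	.	+	.	ID=gene3;Name=MYBPC1
4	rohscan	gene	42500001	42980000	.	+	.	ID=gene4;Name=CACNA2D1
6	rohscan	gene	34000001	34440000	.	+	.	ID=gene5;Name=BMPR1B
6	rohscan	gene	78400001	78500000	.	+	.	ID=gene6;Name=CLOCK
13	rohscan	gene	2000001	2260000	.	+	.	ID=gene7;Name=TASP1
13	rohscan	gene	50900001	51210000	.	+	.	ID=gene8;Name=BMP2
17	rohscan	gene	62000001	62150000	.	+	.	ID=gene9;Name=KDM2B
23	rohscan	gene	42500001	42640000	.	+	.	ID=gene10;Name=MYOM1
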