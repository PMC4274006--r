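combination	n_loci	n_snps	n_sts
ITS	1	19	15
ITS2	1	12	14
LSU_D1_D3	1	11	8
ITS1	1	7	6
rbcL	1	4	2
matK	1	1	3
ITS+LSU_D1_D3	2	30	18
ITS2+LSU_D1_D3	2	23	18
ITS1+LSU_D1_D3	2	18	12
rbcL+matK	2	5	3
ITS+rbcL+matK	3	24	16
ITS2+rbcL+matK	3	17	15
LSU_D1_D3+rbcL+matK	3	16	9
ITS1+rbcL+matK	3	12	7
ITS+LSU_D1_D3+rbcL+matK	4	35	19
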