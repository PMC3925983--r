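primer_id	sequence	length	location	orientation
DYZ1_A	CCATTCGAGACCGTAGCAATT	21	35-16 (5' upstream to HaeIII site)	5'-3'
DYZ1_B	ATTTGATGCCATCCCATGAC	20	763-782	5'-3'
DYZ1_C	TCCTTTGCCTTCCATTCG	18	1668-1685	5'-3'
DYZ1_D	TGCAGTCTTTTCCCTTCGAG	20	2564-2583	5'-3'
DYZ1_E	ATTGGATGGGATTGGAATGA	20	861-880	3'-5'
DYZ1_F	TCGAATGGAAGGCAAAGG	18	1669-1686	3'-5'
DYZ1_G	CGACTGGTACGGACTCCAT	19	2637-2656	3'-5'
DYZ1_H	TGGACAGCCTGGAATAAAGTG	21	3586-3606	3'-5'
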