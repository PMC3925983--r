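name	recognition	overhang
Cac8I	GCNNGC	5'
BseYI	CCCAGC	5'
Bsp1407I	TGTACA	5'
BspHI	TCATGA	3'
ClaI	ATCGAT	3'
DdeI	CTNAG	blunt
EcoRI	GAATTC	5'
ScrFI	CCNGG	3'
VspI	ATTAAT	blunt
BseMII	CTCAG	5'
BsgI	GTGCAG	3'
BtsI	GCAGTG	3'
Eco57I	CTGAAG	3'
GsuI	CTGGAG	3'
Hpy188I	TCNGA	3'
MnlI	CCTC	3'
PflMI	CCANNNNNTGG	3'
SduI	GDGCHC	blunt
BsaBI	GATNNNNATC	blunt
TaqII	GACCGA	3'
MfeI	CAATTG	5'
AcyI	GRCGYC	5'
HgaI	GACGC	5'
Hpy99I	CGWCG	3'
HaeIV	GAYNNNNNRTC	3'
Hin4I	GAYNNNNNVTC	3'
DpnI	GATC	5'
FokI	GGATG	3'
MboI	GATC	5'
ArsI	GACNNNNNNTTYG	5'
BdaI	TGANNNNNNTCA	5'
CspCI	CAANNNNNGTGG	5'
Eco57MI	CTGRAG	5'
SetI	ASST	5'
TspRI	CASTG	5'
ApoI	RAATTY	3'
AsuII	TTCGAA	3'
Eco31I	GGTCTC	blunt
TatI	WGTACW	5'
MboII	GAAGA	3'
CviJI	RGCY	blunt
MslI	CAYNNNNRTG	5'
BccI	CCATC	3'
MaeI	CTAG	3'
SfaNI	GCATC	3'
AlfI	GCANNNNNNTGC	3'
TstI	CACNNNNNNTCC	3'
RsaI	GTAC	3'
BsmAI	GTCTC	3'
BstXI	CCANNNNNNTGG	blunt
XmnI	GAANNNNTTC	5'
MseI	TTAA	3'
NlaIII	CATG	5'
BcgI	CGANNNNNNTGC	5'
BsrDI	GCAATG	5'
BsrI	ACTGG	5'
TspGWI	ACGGA	5'
BsmI	GAATGC	5'
AgsI	TTSAA	5'
FaiI	YATR	3'
PleI	GAGTC	3'
TspDTI	ATGAA	blunt
TspEI	AATT	5'
TfiI	GAWTC	3'
TaqI	TCGA	blunt
HinfI	GANTC	5'
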