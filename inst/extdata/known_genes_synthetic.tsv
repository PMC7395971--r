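gene	protein_change
TP53	p.R175H
TP53	p.R249S
TP53	p.R273C
TP53	p.R273H
APC	
KRAS	p.G12D
KRAS	p.G12V
KRAS	p.G12C
KRAS	p.G13D
EGFR	p.L858R
EGFR	p.T790M
PIK3CA	p.E545K
PIK3CA	p.H1047R
SMAD4	
ARID1A	
CTNNB1	p.S45F
GNAQ	p.Q209L
KMT2C	
BRAF	p.V600E
NRAS	p.Q61K
KIT	p.D816V
MET	
ERBB2	p.S310F
PTEN	
RB1	
ATM	
BRCA1	
BRCA2	
NF1	
FBXW7	p.R465C
STK11	
CDKN2A	
IDH1	p.R132H
NOTCH1	
ALK	p.F1174L
RET	p.M918T
MYC	
VHL	
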