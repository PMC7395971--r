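gene	protein_change
BRAF	p.V600E
BRAF	p.V600K
EGFR	p.L858R
EGFR	p.T790M
EGFR	p.G719A
EGFR	p.L861Q
ERBB2	p.S310F
ERBB2	p.V777L
KIT	p.D816V
KIT	p.V559D
KRAS	p.G12D
KRAS	p.G12V
KRAS	p.G12C
KRAS	p.G12A
KRAS	p.G13D
KRAS	p.Q61H
MET	p.D1228N
MET	p.Y1230H
NRAS	p.Q61K
NRAS	p.Q61R
NRAS	p.G12D
PIK3CA	p.E542K
PIK3CA	p.E545K
PIK3CA	p.H1047R
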