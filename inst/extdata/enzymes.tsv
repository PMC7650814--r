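# Restriction enzymes, REBASE-style: caret marks a within-site cut on the
# top strand; (t/b) gives top/bottom cut distances past the 3' end of an
# asymmetric recognition site (Type IIS).
NciI	CC^SGG
BstXI	CCANNNNN^NTGG
SfcI	C^TRYAG
BsmBI	CGTCTC(1/5)
EcoRI	G^AATTC
BamHI	G^GATCC
HindIII	A^AGCTT
HinfI	G^ANTC
TaqI	T^CGA
DdeI	C^TNAG
AluI	AG^CT
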