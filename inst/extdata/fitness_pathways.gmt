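APOPTOSIS	curated fitness pathway (editable)	CASP3	CASP8	CASP9	BAX	BAK1	BCL2	BCL2L1	MCL1	TP53	BBC3	PMAIP1	FAS	FADD	BID	APAF1	CYCS	DIABLO	XIAP	BIRC5	TNFRSF10B
CELL_CYCLE	curated fitness pathway (editable)	CDK1	CDK2	CDK4	CDK6	CCNA2	CCNB1	CCND1	CCNE1	CDC20	CDC25A	CDC25C	E2F1	RB1	PLK1	AURKA	AURKB	BUB1	MAD2L1	WEE1	CDT1
CHECKPOINT	curated fitness pathway (editable)	TP53	ATM	ATR	CHEK1	CHEK2	MDM2	CDKN1A	CDKN1B	CDKN2A	H2AFX	MDC1	TP53BP1	BRCA1	BRCA2	RAD51	FANCD2	CLSPN	TIMELESS	TIPIN	RPA1
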