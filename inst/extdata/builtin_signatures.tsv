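signature	feature
Hybrid	CDC20
Hybrid	CLSPN
Hybrid	SYTL4
Hybrid	NUSAP1
Hybrid	MELK
Hybrid	CEP55
Hybrid	CKAP2L
Hybrid	PTTG1
Hybrid	IRF3
Hybrid	PREX1
Hybrid	OR5M11
Hybrid	CCNB2
Hybrid	NLRP1
Hybrid	BUB1
Hybrid	NPI
EndoPredictGL	ESR1
EndoPredictGL	ERBB2
EndoPredictGL	BIRC5
EndoPredictGL	RBBP8
EndoPredictGL	UBE2C
EndoPredictGL	IL6ST
EndoPredictGL	AZGP1
EndoPredictGL	DHCR7
EndoPredictGL	MGP
EndoPredictGL	STC2
EndoPredictGL	CALM2
EndoPredictGL	PPIA
EndoPredictGL	OAZ1
EndoPredictGL	RPL37A
EndoPredictGL	PAEP
OncotypeDxGL	MKI67
OncotypeDxGL	AURKA
OncotypeDxGL	BIRC5
OncotypeDxGL	CCNB1
OncotypeDxGL	MYBL2
OncotypeDxGL	ERBB2
OncotypeDxGL	GRB7
OncotypeDxGL	ESR1
OncotypeDxGL	PGR
OncotypeDxGL	BCL2
OncotypeDxGL	SCUBE2
OncotypeDxGL	CTSV
OncotypeDxGL	MMP11
OncotypeDxGL	BAG1
OncotypeDxGL	CD68
OncotypeDxGL	GSTM1
OncotypeDxGL	ACTB
OncotypeDxGL	GUSB
OncotypeDxGL	GAPDH
OncotypeDxGL	RPLP0
OncotypeDxGL	TFRC
Random	CADPS2
Random	PLAU
Random	ACTR3C
Random	PHKG1
Random	RSPRY1
Random	P2RX6P
Random	TIGD6
Random	SPON1
Random	PTPN14
Random	PDZK1
Random	BTBD10
Random	SLC9B2
Random	TRIM71
Random	ADCY6
Random	ALOX15B
NPI+Random	NPI
NPI+Random	PLAU
NPI+Random	ACTR3C
NPI+Random	PHKG1
NPI+Random	RSPRY1
NPI+Random	P2RX6P
NPI+Random	TIGD6
NPI+Random	SPON1
NPI+Random	PTPN14
NPI+Random	PDZK1
NPI+Random	BTBD10
NPI+Random	SLC9B2
NPI+Random	TRIM71
NPI+Random	ADCY6
NPI+Random	ALOX15B
NPI	NPI
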