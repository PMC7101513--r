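name	degree	betweenness
ALB	121	0.131298
INS	110	0.125716
POMC	92	0.018258
NPS	91	0.029010
KNG1	87	0.019268
FOS	82	0.019946
F2	81	0.018713
GNB3	80	0.042513
IL6	78	0.020569
TAC1	78	0.016064
TNF	73	0.020693
BDNF	70	0.024804
EDN1	70	0.018413
EGF	68	0.021209
CRH	66	0.006211
NPY	66	0.006144
SST	64	0.010855
NTS	62	0.024080
HTR7	61	0.011028
NOS3	60	0.019226
CREB1	55	0.024585
MMP9	49	0.027458
TH	46	0.028666
PRL	45	0.028540
CACNA1C	43	0.038877
WDTC1	41	0.026239
ACLY	36	0.052981
CACNA1B	36	0.028122
CACNA1A	33	0.027352
NOTCH1	30	0.023984
ALDH7A1	19	0.025062
CLCN2	13	0.027591
GABRQ	13	0.023171
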