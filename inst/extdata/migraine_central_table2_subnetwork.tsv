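name	degree	betweenness	original_rank
INS	29	0.128	2
ALB	27	0.061	1
FOS	24	0.016	6
F2	24	0.018	7
TAC1	22	0.010	10
IL6	22	0.021	9
SST	22	0.010	17
TNF	21	0.010	11
NPS	21	0.007	4
EDN1	21	0.022	13
BDNF	21	0.020	12
POMC	21	0.007	3
CREB1	21	0.020	21
NPY	20	0.006	16
KNG1	19	0.007	5
HTR7	19	0.010	19
EGF	19	0.008	14
PRL	18	0.062	24
NTS	18	0.007	18
NOS3	18	0.020	20
CRH	18	0.004	15
TH	16	0.060	23
MMP9	14	0.002	29
GNB3	14	0.019	8
WDTC1	13	0.005	26
NOTCH1	11	0.005	30
CACNA1B	6	0.003	28
CACNA1A	6	0.002	29
ALDH7A1	6	0.002	31
CACNA1C	5	0.001	25
ACLY	4	0.001	27
CLCN2	2	0.001	32
GABRQ	2	0.001	33
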