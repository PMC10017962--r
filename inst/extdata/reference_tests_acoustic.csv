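dataset,task,biomarker,n_cn,n_pd,H,p_label,p,OB,eta2,auroc,note
NLS,SS,SPTIME,33,23,8.65,0.01,0.01,down,0.14,0.72,
NLS,SS,SILDUR,33,23,7.87,0.02,0.02,up,0.13,0.72,
NLS,SS,SILVAR,33,23,7.68,0.02,0.02,up,0.12,0.72,
NLS,SS,F0STD,33,23,4.58,0.048,0.048,down,0.07,0.67,
NLS,SS,INTSTD,33,23,13.36,<0.001,0.0005,up,0.22,0.79,
NLS,RP,SILTIME,32,22,5.58,0.03,0.03,up,0.09,0.69,
NLS,RP,SILPERC,32,22,6.72,0.03,0.03,up,0.11,0.69,
NLS,RP,SILSPRAT,32,22,6.72,0.03,0.03,up,0.11,0.71,
NLS,RP,SILDUR,32,22,6.12,0.03,0.03,up,0.10,0.71,
NLS,RP,SILVAR,32,22,5.62,0.03,0.03,up,0.09,0.70,
NLS,RP,F0STD,32,22,5.35,0.03,0.03,down,0.08,0.69,
NLS,RP,INTSTD,32,22,5.17,0.03,0.03,up,0.08,0.69,
GermanPD,TDU,SILTIME,88,88,22.32,<0.001,0.0005,up,0.12,0.71,
GermanPD,TDU,SILPERC,88,88,32.27,<0.001,0.0005,up,0.17,0.75,
GermanPD,TDU,SILSPRAT,88,88,32.27,<0.001,0.0005,up,0.17,0.67,
GermanPD,TDU,SILDUR,88,88,27.63,<0.001,0.0005,up,0.14,0.73,
GermanPD,TDU,F0STD,88,88,16.31,<0.001,0.0005,down,0.09,0.68,
GermanPD,TDU,F1STD,88,88,7.93,0.007,0.007,down,0.04,0.62,
GermanPD,RP,F0STD,88,88,27.52,<0.001,0.0005,down,0.14,0.73,
GermanPD,RP,INTSTD,88,88,18.15,<0.001,0.0005,down,0.09,0.69,
GermanPD,SS,SPTIME,88,88,24.90,<0.001,0.0005,down,0.14,0.72,
GermanPD,SS,SILDUR,88,88,7.69,0.01,0.01,up,0.05,0.62,
GermanPD,SS,F0STD,88,88,21.61,<0.001,0.0005,down,0.12,0.70,
GermanPD,SS,INTSTD,88,88,33.63,<0.001,0.0005,up,0.20,0.75,
Neurovoz,TDU,SPTIME,46,43,15.17,<0.001,0.0005,down,0.16,0.74,
Neurovoz,TDU,SILPERC,46,43,11.60,0.001,0.001,up,0.12,0.71,
Neurovoz,TDU,SILSPRAT,46,43,11.60,0.001,0.001,up,0.12,0.71,
Neurovoz,TDU,SILVAR,46,43,7.03,0.01,0.01,up,0.07,0.62,
ItalianPVS,TDU,SPTIME,35,28,13.23,<0.001,0.0005,up,0.20,0.77,
ItalianPVS,TDU,SILTIME,35,28,14.15,<0.001,0.0005,up,0.22,0.78,
ItalianPVS,TDU,SILPERC,35,28,7.72,0.006,0.006,up,0.11,0.71,
ItalianPVS,TDU,SILSPRAT,35,28,7.72,0.006,0.006,up,0.11,0.71,
ItalianPVS,TDU,SILDUR,35,28,22.11,<0.001,0.0005,up,0.34,0.85,
ItalianPVS,TDU,SILVAR,35,28,14.47,<0.001,0.0005,up,0.23,0.78,
ItalianPVS,TDU,F0STD,35,28,10.56,<0.001,0.0005,down,0.16,0.74,
ItalianPVS,TDU,INTSTD,35,28,32.79,<0.001,0.0005,up,0.52,0.92,task assigned per sample sizes and running text; printed row label ambiguous
ItalianPVS,RP,SILTIME,21,26,7.79,0.02,0.02,up,0.15,0.74,
ItalianPVS,RP,SILPERC,21,26,6.81,0.02,0.02,up,0.12,0.72,
ItalianPVS,RP,SILSPRAT,21,26,6.81,0.02,0.02,up,0.12,0.72,
ItalianPVS,RP,SILDUR,21,26,10.85,0.01,0.01,up,0.22,0.78,
ItalianPVS,RP,SILVAR,21,26,5.54,0.03,0.03,up,0.11,0.70,
ItalianPVS,RP,F0STD,21,26,6.37,0.01,0.01,down,0.12,0.72,direction per running text (lower pitch variability in read speech); printed arrow conflicts
ItalianPVS,RP,INTSTD,21,26,17.23,<0.001,0.0005,up,0.36,0.86,
CzechPD,RP,SILTIME,16,20,9.92,0.005,0.005,up,0.12,0.82,
CzechPD,RP,SILPERC,16,20,9.75,0.002,0.002,up,0.25,0.85,
CzechPD,RP,SILSPRAT,16,20,12.25,0.002,0.002,up,0.33,0.85,
CzechPD,RP,SILDUR,16,20,8.21,0.009,0.009,up,0.21,0.79,
CzechPD,RP,F0STD,16,20,5.92,0.04,0.04,down,0.14,0.74,
CzechPD,RP,INTSTD,16,20,4.69,0.04,0.04,down,0.10,0.72,
CzechPD,RP,SILVAR,16,20,4.69,0.04,0.04,up,0.10,0.72,direction per running text (pause variability higher in PD); printed block garbled
CzechPD,SS,SILTIME,16,20,14.44,0.001,0.001,up,0.39,0.88,
CzechPD,SS,SILPERC,16,20,11.33,0.002,0.002,up,0.30,0.84,
CzechPD,SS,SILSPRAT,16,20,11.33,0.002,0.002,up,0.30,0.84,
CzechPD,SS,SILDUR,16,20,11.33,0.002,0.002,up,0.30,0.84,
CzechPD,SS,F0STD,16,20,6.41,0.03,0.03,down,0.16,0.75,
GITA,RP,F0STD,50,50,8.46,0.01,0.01,down,0.08,0.67,
GITA,TDU,F0STD,50,50,7.46,0.009,0.009,down,0.06,0.57,
GITA,TDU,INTSTD,50,50,7.90,0.009,0.009,down,0.07,0.57,
GITA,TDU,F1STD,50,50,5.18,0.02,0.02,down,0.04,0.56,
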