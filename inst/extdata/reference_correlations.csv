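dataset,task,biomarker,scale,rho,p_label,p,note
NLS,RP,SILTIME,updrs3,0.49,0.01,0.01,
NLS,RP,SILPERC,updrs3,0.51,0.01,0.01,
NLS,RP,SILSPRAT,updrs3,0.51,0.01,0.01,
GermanPD,RP,SPTIME,hy,0.33,0.008,0.008,
GermanPD,RP,SILTIME,hy,0.35,0.007,0.007,
GermanPD,RP,SILSPRAT,hy,0.31,0.007,0.007,
GermanPD,RP,SILDUR,hy,0.32,0.007,0.007,
GermanPD,TDU,RHYSTD,hy,0.38,<0.001,0.0005,
CzechPD,RP,INTSTD,updrs3,-0.60,0.02,0.02,
Neurovoz,TDU,F0STD,updrs3,-0.43,0.04,0.04,
Neurovoz,TDU,F1STD,updrs3,0.42,0.04,0.04,
Neurovoz,SS,SILDUR,updrs3,0.67,0.02,0.02,
ItalianPVS,TDU,SPTIME,updrs3_1,-0.47,0.02,0.02,
ItalianPVS,TDU,SILTIME,updrs3_1,0.63,0.003,0.003,
ItalianPVS,TDU,SILPERC,updrs3_1,0.63,0.003,0.003,
ItalianPVS,TDU,SILSPRAT,updrs3_1,0.63,0.003,0.003,
ItalianPVS,TDU,SILVAR,updrs3_1,0.40,0.048,0.048,
ItalianPVS,TDU,RHYSTD,updrs3_1,0.48,0.018,0.018,
ItalianPVS,RP,RHYSTD,updrs3_1,0.67,<0.001,0.0005,
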