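dataset,task,biomarker,n_cn,n_pd,H,p_label,p,OB,eta2,auroc,note
NLS,SS,RHYSTD,33,23,5.37,0.02,0.02,down,0.08,0.67,
NLS,RP,RHYSTD,32,22,3.88,0.048,0.048,up,0.06,0.65,
GermanPD,SS,WORDCNT,88,88,16.22,<0.001,0.0005,down,0.08,0.68,
GermanPD,SS,SENTCNT,88,88,7.86,0.005,0.005,down,0.04,0.62,
GermanPD,SS,NOUNCNT,88,88,14.11,<0.001,0.0005,down,0.07,0.66,
GermanPD,SS,AUXCNT,88,88,11.85,0.001,0.001,down,0.06,0.65,
GermanPD,SS,NPCNT,88,88,9.96,0.003,0.003,down,0.05,0.64,
GermanPD,SS,PPCNT,88,88,13.50,<0.001,0.0005,down,0.07,0.64,
GermanPD,SS,RHYSTD,88,88,19.35,<0.001,0.0005,down,0.10,0.69,
Neurovoz,TDU,RHYSTD,46,43,15.27,<0.001,0.0005,down,0.16,0.74,
Neurovoz,SS,WORDCNT,46,43,10.56,0.01,0.01,down,0.11,0.74,
Neurovoz,SS,SENTCNT,46,43,13.37,0.003,0.003,down,0.14,0.83,
Neurovoz,SS,NOUNCNT,46,43,7.06,0.01,0.01,down,0.07,0.74,
Neurovoz,SS,VERBCNT,46,43,11.22,0.006,0.006,down,0.11,0.80,
Neurovoz,SS,AUXCNT,46,43,7.11,0.01,0.01,down,0.07,0.74,
Neurovoz,SS,NPCNT,46,43,8.84,0.01,0.01,down,0.09,0.77,
Neurovoz,SS,VPCNT,46,43,6.91,0.01,0.01,down,0.07,0.74,
Neurovoz,SS,RHYSTD,46,43,6.01,0.01,0.01,down,0.06,0.72,
Neurovoz,SS,IU,46,43,5.21,0.02,0.02,down,0.05,0.70,
ItalianPVS,RP,RHYSTD,21,26,16.99,<0.001,0.0005,up,0.35,0.81,
ItalianPVS,TDU,RHYSTD,21,26,3.91,0.047,0.047,up,0.06,0.67,sample sizes as printed
GITA,TDU,RHYSTD,50,50,4.07,0.04,0.04,down,0.03,0.62,
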