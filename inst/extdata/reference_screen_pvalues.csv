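parameter,phase,IH,RT,Ef,SH,ST,QK,FP,OF,OP
"No. of TDE",All,0.01*,0.02*,0.04*,0.13,0.07,0.27,0.09,0.09,0.02*
"No. of TDE",A,0.05,0.10,0.30,0.36,0.15,0.14,0.12,0.31,0.09
"No. of TDE",B,0.12,0.14,0.35,0.52,0.34,0.34,0.29,0.42,0.17
"No. of TDE",C,<0.01**,0.03*,0.05*,0.10,0.04*,0.18,0.04*,0.06,<0.01**
"No. of TDE",D,0.02*,0.11,0.12,0.26,0.11,0.33,0.10,0.18,0.07
CV-VA,All,0.26,0.19,0.38,0.39,0.38,0.99,0.59,0.64,0.39
CV-VA,A,0.34,0.41,0.68,0.73,0.52,0.96,0.68,0.95,0.76
CV-VA,B,0.09,0.06,0.16,0.25,0.18,0.50,0.22,0.26,0.17
CV-VA,C,0.22,0.21,0.32,0.39,0.34,1.00,0.59,0.57,0.25
CV-VA,D,0.08,0.09,0.16,0.29,0.20,0.61,0.24,0.24,0.11
Max-dVA,All,0.07,0.19,0.22,0.14,0.12,0.47,0.26,0.39,0.24
Max-dVA,A,0.05,0.28,0.45,0.28,0.08,0.18,0.10,0.33,0.17
Max-dVA,B,0.03*,0.04*,0.11,0.19,0.08,0.11,0.08,0.14,0.07
Max-dVA,C,0.34,0.52,0.69,0.54,0.42,0.89,0.71,0.89,0.63
Max-dVA,D,0.07,0.18,0.08,0.16,0.13,0.52,0.14,0.16,0.16
Rt-PD,All,0.02*,0.01*,<0.01**,<0.01**,<0.01**,0.09,0.02*,<0.01**,<0.01**
Rt-PD,A,0.82,0.61,0.64,0.54,0.58,0.82,0.81,0.52,0.48
Rt-PD,B,0.12,0.02*,0.06,0.10,0.17,0.39,0.29,0.09,0.14
Rt-PD,C,0.07,0.08,0.12,0.09,0.04*,0.15,0.03*,0.01*,0.04*
Rt-PD,D,0.05,0.04*,0.02*,0.05*,0.09,0.24,0.11,0.02*,0.06
Rt-NJI,All,0.18,0.10,0.05,0.04*,0.05,0.02*,0.05*,0.02*,0.02*
Rt-NJI,A,0.74,0.83,0.78,0.86,0.89,0.64,0.71,0.61,0.74
Rt-NJI,B,0.76,0.22,0.34,0.26,0.66,0.31,0.70,0.42,0.36
Rt-NJI,C,0.07,<0.01**,0.01*,0.06,0.04*,0.05*,0.02*,<0.01**,0.01*
Rt-NJI,D,0.02*,0.13,0.03*,0.04*,0.02*,<0.01**,<0.01**,0.06,0.01*
Lt-PD,All,0.10,0.15,0.04*,0.02*,0.02*,0.19,0.07,0.04*,0.08
Lt-PD,A,0.94,0.97,0.49,0.64,0.72,0.96,0.76,0.61,0.67
Lt-PD,B,0.66,0.33,0.43,0.44,0.71,0.63,0.97,0.47,0.28
Lt-PD,C,0.16,0.19,0.20,0.09,0.05*,0.15,0.06,0.03*,0.10
Lt-PD,D,0.22,0.42,0.20,0.14,0.22,0.63,0.40,0.48,0.50
Lt-NJI,All,0.02*,<0.01**,<0.01**,<0.01**,<0.01**,<0.01**,<0.01**,<0.01**,<0.01**
Lt-NJI,A,0.39,0.05*,0.28,0.21,0.26,0.23,0.31,0.07,0.16
Lt-NJI,B,0.64,0.05*,0.14,0.12,0.47,0.43,0.57,0.16,0.34
Lt-NJI,C,0.49,0.11,0.24,0.54,0.62,0.31,0.38,0.22,0.30
Lt-NJI,D,0.05,0.07,0.05,0.08,0.07,0.01*,0.02*,0.02*,<0.01**
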