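# reference aggregate terms and overall scores (per scenario and study average)
# note: the 45 and 55 mmHg stable-term cells are not derivable from the printed
# panels under any tested convention (likely computed from unrounded internals)
"scenario","configuration","stable","overshoot","undershoot","infusion","effectiveness_term","overall"
"35","pid_aggressive",3.08,7.02,0.67,0.93,3.47,40.61
"35","pid_conservative",2.84,0.97,1.32,0.77,4.68,27.6
"35","stepfis_aggressive",0.51,0.72,0.51,1.62,0.36,1.23
"35","stepfis_conservative",0.78,0.41,0.73,1.26,0.76,2.41
"35","anfis_aggressive",0.53,0.9,0.5,1.18,0.58,1.81
"35","anfis_conservative",0.62,0.11,0.62,0.89,0.58,1.29
"35","adrc_aggressive",2.22,1.6,0.62,0.9,0.85,4.56
"35","adrc_conservative",0.98,0.25,1.13,0.73,1.3,4.01
"35","pfc_aggressive",3.23,1.36,0.66,1.25,1.75,11.36
"35","pfc_conservative",4.37,0,2.05,0.93,28.21,207.45
"45","pid_aggressive",2.87,2.38,0.69,1,3.73,25.9
"45","pid_conservative",1.36,0.9,1.12,0.79,1.47,6.13
"45","stepfis_aggressive",6.56,5.74,0.47,1.55,15.85,227.08
"45","stepfis_conservative",0.75,0.25,0.5,1.04,0.27,0.68
"45","anfis_aggressive",1.31,0.44,0.44,0.98,0.57,1.82
"45","anfis_conservative",0.75,0.14,0.51,0.71,0.29,0.6
"45","adrc_aggressive",0.81,0.92,0.69,0.99,0.73,2.47
"45","adrc_conservative",0.4,0.28,1.08,0.79,0.41,1.05
"45","pfc_aggressive",1.66,1.09,0.66,1.26,1.57,7.33
"45","pfc_conservative",0.96,0.15,1.56,0.96,1.49,5.41
"55","pid_aggressive",1.71,0.96,1.04,1.41,1.22,6.24
"55","pid_conservative",0.33,0.25,1.55,1.19,0.25,0.83
"55","stepfis_aggressive",4.35,4,0.44,1.76,173.65,1833.27
"55","stepfis_conservative",0.45,0.7,0.67,1.32,0.33,1.05
"55","anfis_aggressive",1.28,1.1,0.52,0.74,2.74,9.96
"55","anfis_conservative",0.09,0.04,0.54,0.57,0.1,0.12
"55","adrc_aggressive",1.38,1.01,0.88,1.37,1.26,5.84
"55","adrc_conservative",0.5,0.2,1.49,1.22,0.26,0.9
"55","pfc_aggressive",1.78,0.67,0.58,1.27,1.17,5.04
"55","pfc_conservative",2.48,0.61,0.71,0.94,0.79,3.75
"average","pid_aggressive",2.55,3.45,0.8,1.11,2.81,24.25
"average","pid_conservative",1.51,0.71,1.33,0.92,2.13,11.52
"average","stepfis_aggressive",3.81,3.49,0.47,1.64,63.29,687.19
"average","stepfis_conservative",0.66,0.45,0.63,1.21,0.45,1.38
"average","anfis_aggressive",1.04,0.81,0.49,0.97,1.3,4.53
"average","anfis_conservative",0.49,0.1,0.56,0.72,0.32,0.67
"average","adrc_aggressive",1.47,1.17,0.73,1.08,0.95,4.29
"average","adrc_conservative",0.63,0.24,1.23,0.92,0.66,1.99
"average","pfc_aggressive",2.22,1.04,0.63,1.26,1.5,7.91
"average","pfc_conservative",2.6,0.25,1.44,0.94,10.16,72.21
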