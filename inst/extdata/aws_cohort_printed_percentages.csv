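participant_id,repetition_pct,prolongation_pct,block_pct
AWS01,1.39,0.00,6.83
AWS02,3.32,2.03,15.50
AWS03,0.43,0.00,1.28
AWS04,0.81,0.54,6.11
AWS05,0.13,0.00,3.51
AWS06,1.38,0.58,2.77
AWS07,0.58,0.00,1.16
AWS08,2.73,0.11,11.02
AWS09,2.45,0.12,0.70
AWS10,1.96,0.09,1.22
AWS11,1.61,1.21,9.68
AWS12,1.43,0.00,4.15
AWS13,1.51,0.50,2.27
AWS14,1.89,1.06,1.77
AWS15,0.12,0.75,2.25
AWS16,5.37,1.86,1.64
AWS17,1.35,0.98,5.28
AWS18,1.32,0.13,3.69
AWS19,1.69,0.85,3.99
AWS20,0.12,0.12,4.06
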