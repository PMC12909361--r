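parameter,value,unit,description
ref_weight,70,kg,reference body weight
V_plasma,2.6,L,plasma volume
V_lymph,5.2,L,total lymph volume
V_tight,10.14,L,interstitial fluid volume of tight-endothelium tissues (0.65 x 15.6 L ISF)
V_leaky,5.46,L,interstitial fluid volume of leaky-endothelium tissues (0.35 x 15.6 L ISF)
L,0.12083333333333333,L/h,total lymph flow (2.9 L/day)
L1,0.039875,L/h,lymph flow to tight tissues (0.33 x L)
L2,0.08095833333333333,L/h,lymph flow to leaky tissues (0.67 x L)
sigma_L,0.2,dimensionless,lymphatic capillary reflection coefficient
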