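name,density,H,C,N,O,Na,Mg,P,S,Cl,Ar,K,Ca
water,1.000,0.111894,0,0,0.888106,0,0,0,0,0,0,0,0
air,0.0012047,0,0.000124,0.755267,0.231781,0,0,0,0,0,0.012828,0,0
lung_deflated,0.26,0.103,0.105,0.031,0.749,0.002,0,0.002,0.003,0.003,0,0.002,0
adipose,0.95,0.114,0.598,0.007,0.278,0.001,0,0,0.001,0.001,0,0,0
breast,0.99,0.109,0.506,0.023,0.358,0.001,0,0.001,0.001,0.001,0,0,0
soft_tissue,1.03,0.105,0.256,0.027,0.602,0.001,0,0.002,0.003,0.002,0,0.002,0
muscle,1.05,0.102,0.143,0.034,0.710,0.001,0,0.002,0.003,0.001,0,0.004,0
brain,1.04,0.107,0.145,0.022,0.712,0.002,0,0.004,0.002,0.003,0,0.003,0
liver,1.06,0.103,0.186,0.028,0.671,0.002,0,0.003,0.003,0.002,0,0.002,0
eye,1.026,0.096,0.070,0.017,0.812,0.002,0,0,0.001,0.002,0,0,0
csf,1.007,0.111,0,0,0.880,0.005,0,0,0,0.004,0,0,0
spongiosa,1.18,0.085,0.404,0.058,0.368,0.001,0.001,0.034,0.002,0.002,0,0.001,0.044
skull_base_bone,1.33,0.070,0.300,0.050,0.400,0.001,0.001,0.055,0.002,0.001,0,0,0.120
cranial_bone,1.61,0.050,0.212,0.040,0.435,0.001,0.002,0.081,0.003,0,0,0,0.176
cortical_bone,1.92,0.034,0.155,0.042,0.435,0.001,0.002,0.103,0.003,0,0,0,0.225
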