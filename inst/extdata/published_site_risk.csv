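row,TD0,TD1,TD2,TD3,contribution
RI-As,7.63,13.5,7.86,11.56,1.63
RI-Cd,49.00,367.91,159.13,223.98,32.08
RI-Cr,1.71,13.81,13.45,12.26,1.65
RI-Cu,73.80,70.59,26.66,34.48,8.24
RI-Ni,2.29,5.32,5.21,6.81,0.79
RI-Pb,257.40,417.43,334.50,373.65,55.45
RI-Zn,0.53,1.22,1.41,1.02,0.17
RI,392.35,889.78,548.21,663.76,NA
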