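site,metal,mean,sd
TD0,As,6.94,2.42
TD1,As,12.28,4.32
TD2,As,7.15,3.44
TD3,As,10.52,3.96
TD0,Cd,0.17,0.08
TD1,Cd,1.25,0.66
TD2,Cd,0.54,0.34
TD3,Cd,0.76,0.25
TD0,Cr,47.24,20.04
TD1,Cr,381.91,176.75
TD2,Cr,371.90,169.15
TD3,Cr,339.05,174.71
TD0,Cu,338.00,184.21
TD1,Cu,323.28,157.59
TD2,Cu,122.10,36.15
TD3,Cu,157.91,36.37
TD0,Ni,34.17,7.63
TD1,Ni,79.51,55.13
TD2,Ni,77.89,44.53
TD3,Ni,101.79,67.16
TD0,Pb,756.76,221.91
TD1,Pb,1227.24,360.65
TD2,Pb,983.42,292.03
TD3,Pb,1098.53,349.17
TD0,Zn,33.43,18.91
TD1,Zn,77.17,36.37
TD2,Zn,89.23,23.84
TD3,Zn,64.67,16.73
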