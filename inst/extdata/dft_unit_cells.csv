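polymorph,pressure_GPa,a,b,c,alpha,beta,gamma,volume_A3,energy_eV
Form I,0.0,8.087,11.900,5.421,90.0,90.0,90.00,521.65,-323.555
Form II,0.0,9.438,5.199,11.218,90.0,109.0,90.00,520.48,-323.464
Form III,2.6,7.949,10.511,5.348,90.0,90.0,90.00,446.83,-322.858
Form III,4.2,7.874,10.315,5.288,90.0,90.0,90.00,429.46,-322.456
Form IV,1.7,8.073,5.402,10.927,90.0,95.8,90.00,474.08,-323.157
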