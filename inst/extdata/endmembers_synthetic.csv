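water_mass,temperature,salinity,oxygen,phosphate,nitrate,silicate
STW,15.0,35.50,220,0.45,5.0,3
ESSW,12.5,34.90,25,2.40,32.0,25
AAIW,4.5,34.30,270,1.90,27.0,10
UCDW,2.5,34.62,170,2.30,33.0,90
PDW,1.9,34.68,110,2.60,37.0,150
LCDW,1.3,34.72,200,2.20,32.0,120
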