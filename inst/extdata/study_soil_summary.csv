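parameter,unit,minimum,median,maximum,mean_arith,sd_arith,mean_geo,sd_geo,bv,sv,cv_printed
pH,1,4.57,5.78,7.22,5.84,0.76,5.79,1.14,5.53,NA,0.13
SOM,g/kg,12.3,27.6,35.8,27.1,4.24,26.7,1.21,12.3,NA,0.16
DCB-Al,g/kg,146,0.63,2.84,0.80,0.46,0.66,3.81,0.44,NA,0.58
DCB-Fe,g/kg,537,1.69,5.46,1.87,0.96,1.55,3.35,0.67,NA,0.52
Avail-N,mg/kg,28.0,59.6,90.8,59.4,17.1,56.9,0.36,58.3,NA,0.29
Avail-P,mg/kg,0.01,0.03,0.13,0.04,0.03,0.03,0.02,0.03,NA,0.77
Avail-K,mg/kg,23.0,58.8,211,80.3,52.6,65.5,1.92,69.1,NA,0.65
Cd,mg/kg,0.25,19.0,69.4,22.1,19.6,11.3,5.31,0.41,0.30,1.94
Cr,mg/kg,61.6,106,728,151,144,121,1.79,33.9,150,1.19
Cu,mg/kg,0.99,27.9,354,52.3,75.9,27.8,3.64,8.56,50.0,3.02
Pb,mg/kg,31.0,64.8,446,115,105,88.2,2.60,32.7,90.0,1.12
V,mg/kg,101,462,2434,563,527,409,2.21,95.6,130,1.29
Zn,mg/kg,119,266,1742,453,434,329,2.17,118,200,1.32
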