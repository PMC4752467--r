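analyte,wavelength,slope,intercept,r_squared,lod,loq,range_low,range_high
UR,265,33.41,16.38,0.9998,0.15,0.58,0.63,6.30
AD,260,11.41,15.28,0.9998,0.37,1.63,1.92,19.2
CGA,330,21.28,59.83,0.9997,0.15,0.58,1.20,24.0
CFA,330,30.76,78.35,0.9997,0.10,0.41,1.80,36.0
CCA,335,29.94,123.6,0.9997,0.11,0.60,6.60,132
LGR,350,18.78,30.65,0.9998,0.26,0.98,14.3,360
LG,350,20.95,88.50,0.9996,0.20,0.90,3.00,30.0
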