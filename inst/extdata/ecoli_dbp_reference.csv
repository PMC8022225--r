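protein,mass_kda,copies_per_cell,dstar_mobile,d_free,pct_long_lived,pct_transient,pct_free,footprint_bp,dfree_measured
MukBEF,1006,100,0.44,1.2,58,24,18,10,TRUE
RNAP,478,4000,0.36,2.7,45,48,7,70,TRUE
Gyrase,424,600,0.35,2.4,55,38,7,100,FALSE
TopoIV,366,80,0.40,2.7,37,52,11,10,FALSE
UvrA,270,80,0.36,3.4,43,51,6,10,FALSE
MutS,248,100,0.37,3.7,26,68,6,10,FALSE
LacI,220,40,0.40,3.3,41,55,4,10,TRUE
Pol1,128,500,1.04,6.6,4,58,37,10,TRUE
LigA,102,100,1.18,6.9,7,56,37,10,TRUE
H-NS,87,20000,0.41,8.0,73,27,0.1,30,FALSE
HU,48,30000,0.33,12.6,23,77,0.4,36,FALSE
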