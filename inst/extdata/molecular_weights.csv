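id,molecular_weight,approx
GLC,180.16,false
glucose,180.16,false
ATP,507.18,false
ADP,427.20,false
AMP,347.22,false
G6P,260.14,false
glucose 6-phosphate,260.14,false
F6P,260.14,false
fructose 6-phosphate,260.14,false
F16bP,340.12,false
FBP,340.12,false
"fructose 1,6-bisphosphate",340.12,false
DHAP,170.06,false
GAP,170.06,false
TRIO,170.06,true
NAD,663.43,false
NADH,665.44,false
BPG,266.04,false
P3G,186.06,false
P2G,186.06,false
PEP,168.04,false
PYR,88.06,false
pyruvate,88.06,false
G3P,172.07,false
GLY,92.09,false
glycerol,92.09,false
G1P,260.14,false
UTP,484.14,false
UDP,404.16,false
UDPG,566.30,false
T6P,422.28,false
TRH,342.30,false
trehalose,342.30,false
GLYG,666.58,true
glycogen,666.58,true
HXK1,53738,false
HXK2,53944,false
GLK1,55377,false
PGI1,61299,false
PFK,107974,true
PFK1,107974,false
PFK2,104622,false
FBA1,39621,false
TPI1,26795,false
TDH1,35750,false
TDH2,35847,false
TDH3,35747,false
PGK1,44738,false
GPM1,27608,false
ENO1,46816,false
ENO2,46914,false
CDC19,54544,false
PYK2,55195,false
GPD1,42869,false
GPD2,49414,false
GPP1,27946,false
GPP2,27815,false
PGM1,63088,false
PGM2,63071,false
UGP1,55989,false
TPS1,56147,false
TPS2,102939,false
GSY1,80539,false
GSY2,80989,false
PDC1,61495,false
PDC5,61910,false
PDC6,61581,false
ADH1,36849,false
ADH5,37569,false
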