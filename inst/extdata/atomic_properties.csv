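# Pauling electronegativities and IUPAC standard atomic weights
# (conventional values; abridged to common organic/bioinorganic elements)
symbol,electronegativity,atomic_mass
H,2.20,1.008
Li,0.98,6.94
Be,1.57,9.012
B,2.04,10.81
C,2.55,12.011
N,3.04,14.007
O,3.44,15.999
F,3.98,18.998
Na,0.93,22.990
Mg,1.31,24.305
Al,1.61,26.982
Si,1.90,28.085
P,2.19,30.974
S,2.58,32.06
Cl,3.16,35.45
K,0.82,39.098
Ca,1.00,40.078
Fe,1.83,55.845
Cu,1.90,63.546
Zn,1.65,65.38
As,2.18,74.922
Se,2.55,78.971
Br,2.96,79.904
I,2.66,126.904
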