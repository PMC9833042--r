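# Henry's-law solubility of CO2 and O2 in pure water, uM per ubar partial pressure.
# CO2: Carroll, Slupsky & Mather (1991) J Phys Chem Ref Data 20:1201.
# O2:  Benson & Krause (1984) Limnol Oceanogr 29:620.
# Converted from mol L-1 atm-1 (1 atm = 1013250 ubar).
temperature	co2	o2
0	0.0754009	0.00215149
5	0.0626696	0.00188502
10	0.0525043	0.00167777
15	0.0446089	0.00150012
20	0.0382927	0.00136195
25	0.0329632	0.00124352
30	0.0286208	0.00114483
35	0.0250678	0.00107574
40	0.0222058	0.00101653
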