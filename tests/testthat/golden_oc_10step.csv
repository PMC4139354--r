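# law=oc
# P0=225000000.0
# K0=250000000.0
# r=1e-13
# L=5000000000.0
# a=0
# b=0
# t0=1
# t_end=11
year,P,K
1,225000000,250000000
2,225000562.5,250012500
3,225001125.27000067,250025005.96875
4,225001688.31013227,250037517.90909937
5,225002251.62052506,250050035.82389885
6,225002815.20130944,250062559.71600053
7,225003379.05261585,250075089.58825788
8,225003943.17457476,250087625.4435257
9,225004507.56731674,250100167.28466019
10,225005072.23097241,250112715.11451885
11,225005637.16567245,250125268.93596062
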