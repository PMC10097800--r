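# example constant-set config for read_constant_sets(); same values as
# builtin_constant_sets()
name,C,alpha,beta
GW,3.62e-7,2.416,0.785
HO,1.8e-8,1.991,0.765
ZT,1.228e-7,1.9918,0.6606
FZ,1.745e-8,1.963,0.7762
FT-M,4.256e-24,10.2860,2.8073
FT-L,1.000e-9,1.8277,0.5392
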