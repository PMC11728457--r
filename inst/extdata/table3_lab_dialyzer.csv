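parameter,value,unit
fp,0.77,-
alpha,0.083,-
delta,63,um
lhf,15,cm
dhf,190,um
d,140,um
Nhf,90,-
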