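series,manufacturer,delta_um,dhf_um,lhf_cm,d_um
Nephral ST,Baxter,70,210,25,45.5
FX,Fresenius,70,210,20,35.0
Diacap Pro,B. Braun,65,200,20,37.0
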