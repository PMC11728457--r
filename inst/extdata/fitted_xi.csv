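series,manufacturer,xi
Nephral ST,Baxter,0.42
FX,Fresenius,0.45
Diacap Pro,B. Braun,0.8
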