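series,dialyzer_id,Smb_m2,Nhf
Nephral ST,ST 200,1.05,6400
Nephral ST,ST 300,1.30,7900
Nephral ST,ST 400,1.65,10000
Nephral ST,ST 500,2.15,13000
FX,FX 5,1.0,7600
FX,FX 8,1.4,10600
FX,FX 10,1.8,13600
Diacap Pro,Pro 08H,0.8,6400
Diacap Pro,Pro 13H,1.3,10400
Diacap Pro,Pro 16H,1.6,12700
Diacap Pro,Pro 19H,1.9,15100
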