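membrane_id,fp,alpha,xi,W
PSF,0.60,0.049,2.7e-5,0.55
PSF-PEG,0.67,0.081,0.007,0.62
PSF-PVP,0.78,0.086,0.056,0.74
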