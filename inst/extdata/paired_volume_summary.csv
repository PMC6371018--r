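quantity,n,mean_ml,sd_ml
maa_tumor_volume,12,695,275
y90_tumor_volume,12,786,462
difference,12,-91,383
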