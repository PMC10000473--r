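role,count
covariate,12
conversion,1
gain_threshold,239
initial_value,24
time_constant,40
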