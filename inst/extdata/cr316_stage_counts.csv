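stage,n
remaining_after_standardization,216
base,8
specific,9
stimulus,15
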