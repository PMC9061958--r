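group,A,C,G,T
Count Group 1,38514,24631,25685,38249
Count Group 2,38550,24635,25700,38288
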