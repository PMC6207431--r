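region,month,temp_c
Southeast,2,9.3
Northeast,2,-3.8
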