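region,n_raw,n_valid_printed
Taoyuan,155674,154305
Hsinchu,72743,64539
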