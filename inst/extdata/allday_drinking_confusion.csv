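truth,drink,not_drink
drink,26,14
not_drink,10,5689
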