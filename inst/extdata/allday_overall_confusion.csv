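truth,eat,drink,other
eat,150,0,66
drink,5,24,11
other,79,10,5380
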