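class,precision,recall,f1,support
eat,0.39,0.77,0.52,552
drink,0.37,0.62,0.46,81
other,0.99,0.93,0.96,10737
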