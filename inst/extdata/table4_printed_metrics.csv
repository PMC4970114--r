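class,precision,recall,f1
eat_sit,100.00,100.00,100.00
sedentary,100.00,100.00,100.00
eat_walk,100.00,99.26,99.63
walk,99.54,100.00,99.77
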