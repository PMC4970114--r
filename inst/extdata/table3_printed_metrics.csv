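class,precision,recall,f1
eat_sit,96.58,96.58,96.58
sedentary,98.52,97.66,98.09
eat_walk,93.14,95.20,94.16
walk,93.42,94.28,93.85
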