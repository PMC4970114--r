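class,eat_sit,sedentary,eat_walk,walk
eat_sit,322,0,0,0
sedentary,0,1155,0,0
eat_walk,0,0,269,2
walk,0,0,0,437
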