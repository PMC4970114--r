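class,eat_sit,sedentary,eat_walk,walk
eat_sit,310,9,3,0
sedentary,11,1128,0,16
eat_walk,0,0,256,15
walk,0,6,17,414
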