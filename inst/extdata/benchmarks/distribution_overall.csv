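emotion,count,percentage
good,12515,38.27
joy,3965,12.13
surprise,109,0.33
anticipate,30,0.09
neutral,8296,25.37
fear,3633,11.11
disgust,2635,8.06
sadness,889,2.72
anger,626,1.91
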