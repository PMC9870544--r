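emotion,official_count,official_percentage,personal_count,personal_percentage
good,3149,49.12,9292,35.59
joy,736,11.48,3209,12.29
surprise,3,0.05,106,0.41
anticipate,1,0.02,29,0.11
neutral,900,14.04,7344,28.13
fear,1176,18.34,2448,9.38
disgust,249,3.88,2368,9.07
sadness,74,1.15,809,3.10
anger,123,1.92,500,1.92
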