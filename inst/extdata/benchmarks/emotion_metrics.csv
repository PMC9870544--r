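class,precision,recall,f1
Good,0.71,0.91,0.79
Joy,0.58,0.97,0.73
Surprise,0.92,0.67,0.77
Anticipate,0.67,0.11,0.19
Neutral,0.86,0.66,0.74
Disgust,0.94,0.68,0.79
Fear,0.94,0.85,0.89
Anger,0.73,0.45,0.56
Sadness,0.92,0.67,0.78
Macro average,0.81,0.66,0.69
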