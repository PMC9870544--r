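class,precision,recall,f1
Positive,0.70,0.98,0.82
Neutral,0.86,0.66,0.74
Negative,0.93,0.73,0.82
Macro average,0.83,0.79,0.79
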