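group,sentiment,percentage,precision_dp
overall,positive,50.83,2
overall,neutral,25.37,2
overall,negative,23.80,2
official,positive,60.7,1
official,neutral,14.0,1
official,negative,25.3,1
personal,positive,48.4,1
personal,neutral,28.1,1
personal,negative,23.5,1
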