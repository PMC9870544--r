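不
没
没有
无
非
别
勿
未
莫
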