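日报
晚报
电视台
广播
电台
官方
政府
发布
新闻
卫健委
疾控
委员会
网信
融媒体
客户端
传媒
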