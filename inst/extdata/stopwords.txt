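的
了
是
在
我
有
和
就
不
人
都
一
上
也
很
到
说
要
去
你
会
着
没有
自己
这
那
吧
啊
吗
呢
与
及
而
被
让
对
从
个
中
为
地
得
他
她
它
们
之
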