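天空
云朵
街角
清晨
午后
书页
风铃
台阶
行路
路灯
树影
车站
窗台
茶杯
雨伞
地图
桥边
菜园
货架
站台
日历
钟表
棋盘
画框
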