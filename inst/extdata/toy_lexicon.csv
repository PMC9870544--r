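word,code,intensity,polarity
高兴,PA,7,1
快乐,PA,7,1
开心,PA,5,1
欢喜,PA,5,1
愉快,PA,5,1
喜悦,PA,7,1
兴奋,PA,7,1
舒心,PE,5,1
踏实,PE,5,1
安心,PE,5,1
轻松,PE,3,1
敬佩,PD,5,1
尊敬,PD,5,1
佩服,PD,5,1
英明,PH,5,1
优秀,PH,5,1
美好,PH,5,1
出色,PH,5,1
信任,PG,5,1
可靠,PG,5,1
喜欢,PB,5,1
热爱,PB,7,1
心爱,PB,5,1
祝福,PK,5,1
保佑,PK,5,1
愤怒,NA,7,2
生气,NA,5,2
恼火,NA,5,2
气愤,NA,7,2
暴怒,NA,9,2
悲伤,NB,7,2
难过,NB,5,2
伤心,NB,7,2
悲痛,NB,9,2
失望,NJ,5,2
绝望,NJ,9,2
内疚,NH,5,2
惭愧,NH,5,2
思念,PF,5,2
牵挂,PF,5,2
慌张,NI,5,2
恐慌,NI,7,2
惊慌,NI,7,2
害怕,NC,5,2
恐惧,NC,7,2
畏惧,NC,5,2
担心,NC,3,2
紧张,NG,5,2
忐忑,NG,5,2
担忧,NG,5,2
烦恼,ND,5,2
讨厌,ND,5,2
厌恶,ND,7,2
憎恨,NE,7,2
痛恨,NE,7,2
谴责,NN,5,2
指责,NN,5,2
埋怨,NN,3,2
嫉妒,NK,5,2
怀疑,NL,3,2
质疑,NL,3,2
惊讶,PC,5,1
吃惊,PC,5,1
震惊,PC,7,1
惊奇,PC,5,1
意外,PC,3,1
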