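上	一
下	一
不	一
中	丨
为	丶
乏	丿
乐	丿
乱	乙
乳	乙
予	乙
二	二
于	二
亚	二
产	亠
亭	亠
人	人
仍	亻
优	亻
伴	亻
位	亻
体	亻
作	亻
例	亻
侧	亻
修	亻
兄	儿
入	入
全	入
关	八
其	八
内	冂
冠	冖
况	冫
减	冫
凹	凵
出	凵
切	刀
利	刂
前	刂
剖	刂
力	力
功	力
加	力
助	力
化	匕
匹	匚
区	匚
匿	匚
半	十
占	卜
卡	卜
压	厂
双	又
反	又
发	又
口	口
可	口
史	口
右	口
司	口
合	口
吐	口
向	口
否	口
吲	口
呕	口
哑	口
哮	口
喘	口
嗜	口
嘶	口
囊	口
因	囗
固	囗
地	土
垂	土
垫	土
塞	土
增	土
声	士
复	夂
外	夕
多	夕
大	大
头	大
定	宀
宫	宀
家	宀
富	宀
寒	宀
尔	小
尼	尸
尾	尸
尿	尸
左	工
巩	工
帕	巾
常	巾
平	干
年	干
库	广
开	廾
异	廾
往	彳
征	彳
律	彳
微	彳
心	心
急	心
性	忄
恶	心
患	心
悸	忄
情	忄
慢	忄
扁	户
手	手
托	扌
折	扌
指	扌
损	扌
提	扌
摘	扌
断	斤
族	方
无	无
既	旡
明	日
显	日
晕	日
曾	曰
月	月
有	月
服	月
期	月
未	木
本	木
术	木
松	木
林	木
染	木
查	木
桃	木
梗	木
检	木
森	木
椎	木
欣	欠
正	止
死	歹
母	母
比	比
毛	毛
氢	气
水	水
治	氵
泌	氵
泡	氵
泼	氵
洛	氵
溴	氵
满	氵
炎	火
点	灬
热	灬
父	父
牛	牛
特	牜
状	犬
现	王
用	用
甲	田
畏	田
疗	疒
疝	疒
疮	疒
病	疒
症	疒
痛	疒
痤	疒
瘤	疒
癌	疒
白	白
的	白
皮	皮
盘	皿
眼	目
睡	目
矫	矢
石	石
硝	石
硬	石
确	石
示	示
视	见
祖	礻
程	禾
空	穴
窦	穴
管	竹
米	米
粗	米
糖	米
紊	糸
素	糸
索	糸
紫	糸
红	纟
纹	纟
经	纟
结	纟
综	纟
缺	缶
美	羊
考	耂
者	耂
耳	耳
肝	月
肢	月
肤	月
肥	月
肪	月
肺	月
肾	月
肿	月
胀	月
胃	月
胆	月
背	月
胍	月
胖	月
胺	月
能	月
脂	月
脏	月
脑	月
脸	月
腰	月
腹	月
腺	月
腿	月
膜	月
膨	月
自	自
节	艹
苯	艹
菲	艹
薄	艹
虑	虍
蝶	虫
血	血
行	行
补	衤
要	覀
见	见
规	见
觉	见
角	角
认	讠
诊	讠
诱	讠
起	走
跳	足
辅	车
达	辶
进	辶
退	辶
部	阝
酸	酉
重	里
野	里
金	金
钠	钅
锁	钅
长	长
间	门
阑	门
阿	阝
降	阝
院	阝
除	阝
陷	阝
隆	阝
隐	阝
隔	阝
面	面
鞍	革
音	音
颈	页
额	页
颞	页
食	食
饮	饣
马	马
骨	骨
高	高
鸣	鸟
麦	麦
黄	黄
鼻	鼻
疼	疒
痒	疒
疲	疒
咳	口
嗽	口
喉	口
晨	日
夜	夕
汗	氵
渴	氵
麻	麻
胸	月
闷	门
气	气
短	矢
是	日
在	土
和	禾
与	一
及	又
或	戈
后	口
再	冂
次	冫
天	大
日	日
时	日
分	刀
秒	禾
眩	目
呈	口
它	宀
疾	疒
医	匚
药	艹
片	片
目	目
舌	舌
齿	齿
骼	骨
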