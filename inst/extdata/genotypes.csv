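cultivar,origin,area,allele1,allele2
Baixing 10-38,"Beijing, China",NorthChina,S9,S10
Beianhe,"Beijing, China",NorthChina,S9,S17
Beishandabian,"Beijing, China",NorthChina,S10,S53
Beizhaihongxing,"Beijing, China",NorthChina,S93,S103
Chuanling,"Beijing, China",NorthChina,S8,S53
Dabada,"Beijing, China",NorthChina,S36,
Fangshanhongxing,"Beijing, China",NorthChina,S11,
Fangshanxiangbai,"Beijing, China",NorthChina,S17,S53
Guajiayutianhexiangbai,"Beijing, China",NorthChina,S8,S17
H20-5,"Beijing, China",NorthChina,S9,S95
H21-25,"Beijing, China",NorthChina,S23,S53
H23-37,"Beijing, China",NorthChina,S14,S66
H23-43,"Beijing, China",NorthChina,S14,S66
H23-44,"Beijing, China",NorthChina,S14,S66
H-48,"Beijing, China",NorthChina,S8,S52
Honghuomeizi,"Beijing, China",NorthChina,S8,S53
Huangjianzui,"Beijing, China",NorthChina,S2,S66
Jingcuihong,"Beijing, China",NorthChina,S10,S11
Jingfeihong,"Beijing, China",NorthChina,S8,S11
P35-146,"Beijing, China",NorthChina,S8,S30
Jingjia No.1,"Beijing, China",NorthChina,S24,S49
Jingjia No.2,"Beijing, China",NorthChina,S24,S93
Jingluofeng,"Beijing, China",NorthChina,S11,S102
Jingluohong,"Beijing, China",NorthChina,S8,S95
Jingren No.1,"Beijing, China",NorthChina,S98,
Jingren No.2,"Beijing, China",NorthChina,S8,
Jingren No.3,"Beijing, China",NorthChina,S103,
Jingren No.4,"Beijing, China",NorthChina,S95,
Jingren No.5,"Beijing, China",NorthChina,S24,
Jingxianghong,"Beijing, China",NorthChina,S10,S11
Jingzaohong,"Beijing, China",NorthChina,S9,S36
Longquanwuxiangbai,"Beijing, China",NorthChina,S53,S106
Luotuohuang,"Beijing, China",NorthChina,S8,S11
Mituoluo,"Beijing, China",NorthChina,S11,
P51-54,"Beijing, China",NorthChina,S11,S17
Pingguohong,"Beijing, China",NorthChina,S8,S66
Shanbaixing,"Beijing, China",NorthChina,S17,S53
Shanhuangxing,"Beijing, China",NorthChina,S8,S11
Xiaoyubada,"Beijing, China",NorthChina,S23,S53
Yingchun,"Beijing, China",NorthChina,S24,S36
Zaoxiangbai,"Beijing, China",NorthChina,S10,S53
Zhuyaozi,"Beijing, China",NorthChina,S10,S35
Guanlaoyelian,"Tianjin province, China",NorthChina,S8,S16
Wanxiangbai,"Tianjin province, China",NorthChina,S17,S53
Cangzaotian No.1,"Hebei province, China",NorthChina,S11,S49
Chuanzhihong,"Hebei province, China",NorthChina,S8,S24
Dafeng,"Hebei province, China",NorthChina,S8,S94
Erhongxing,"Hebei province, China",NorthChina,S11,S17
Ganyu,"Hebei province, China",NorthChina,S8,S16
Jiguang,"Hebei province, China",NorthChina,S8,S9
Jinyu,"Hebei province, China",NorthChina,S13,S52
Longwangmao,"Hebei province, China",NorthChina,S11,S103
Muguaxing,"Hebei province, China",NorthChina,S11,S16
Qingmisha,"Hebei province, China",NorthChina,S9,S44
Shizixing,"Hebei province, China",NorthChina,S10,S53
Tianedan,"Hebei province, China",NorthChina,S9,S16
Xingtaidahongxing,"Hebei province, China",NorthChina,S17,S36
Xingtaihongjiexing,"Hebei province, China",NorthChina,S8,S97
You No.1,"Hebei province, China",NorthChina,S11,S103
You No.2,"Hebei province, China",NorthChina,S11,
Zaohongxing,"Hebei province, China",NorthChina,S36,
Zaohuang,"Hebei province, China",NorthChina,S9,S53
Guanyelian,"Shanxi province, China",NorthChina,S28,
Hongbada,"Henan province, China",CentralChina,S101,
Lixing,"Henan province, China",CentralChina,S40-1,
Mixiangxing,"Henan province, China",CentralChina,S11,S15
Yangshaohuang No.1,"Henan province, China",CentralChina,S13,S102
Yangshaohuang No.2,"Henan province, China",CentralChina,S36,S102
Yuhankui,"Henan province, China",CentralChina,S11,S107
Yuzaoguan,"Henan province, China",CentralChina,S9,S53
Badou,"Anhui, China",EastChina,S36,S102
Caizihuang,"Shandong province, China",EastChina,S11,S16
Honghebao,"Shandong province, China",EastChina,S9,S16
Hongjinzhen,"Shandong province, China",EastChina,S96,
Jinkaite,"Shandong province, China",EastChina,S11,S104
Kuijin,"Shandong province, China",EastChina,S11,S102
Laoshanhong,"Shandong province, China",EastChina,S11,
Pingdingzhen,"Shandong province, China",EastChina,S12,S36
Qingdaodahong,"Shandong province, China",EastChina,S11,
Zaoyu,"Shandong province, China",EastChina,S20,
Dongning No.1,"Heilongjiang province, China",NortheastChina,S16,S100
Dongning No.2,"Heilongjiang province, China",NortheastChina,S100,
Baixing,"Liaoning province, China",NortheastChina,S10,
Daxingmei,"Liaoning province, China",NortheastChina,S8,
Guofeng,"Liaoning province, China",NortheastChina,S8,S18-2
Caoxing,"Gansu province, China",NorthwestChina,S8,S17
Dajiexing,"Gansu province, China",NorthwestChina,S16,
Dapiantou,"Gansu province, China",NorthwestChina,S36,S102
Zhupishui,"Gansu province, China",NorthwestChina,S8,
Taoxing,"Ningxia province, China",NorthwestChina,S16,
Meixing,"Qinghai province, China",NorthwestChina,S25,
Caopixing,"Shaanxi province, China",NorthwestChina,S16,
Haidongxing,"Shaanxi province, China",NorthwestChina,S16,
Jidanxing,"Shaanxi province, China",NorthwestChina,S25,S26
Lanzhuhong,"Shaanxi province, China",NorthwestChina,S16,S23
Lingtonghongxing,"Shaanxi province, China",NorthwestChina,S101,
Lintonghongxing No.2,"Shaanxi province, China",NorthwestChina,S16,
Liquanerzhuanzi,"Shaanxi province, China",NorthwestChina,S16,
Machuanling,"Shaanxi province, China",NorthwestChina,S11,S16
Niujiaobangzi,"Shaanxi province, China",NorthwestChina,S105,
Niujiaohuang,"Shaanxi province, China",NorthwestChina,S105,
Qinwang,"Shaanxi province, China",NorthwestChina,S40-2,
Touwojie,"Shaanxi province, China",NorthwestChina,S16,
Xinong 25,"Shaanxi province, China",NorthwestChina,S10,S36
Yinxiangbai,"Shaanxi province, China",NorthwestChina,S36,S53
Zaotianhe,"Shaanxi province, China",NorthwestChina,S16,S105
Zhanggongyuan,"Shaanxi province, China",NorthwestChina,S24,S25
Ake,"Xinjiang, China",Xinjiang,S12,S66
Chibangzi,"Xinjiang, China",Xinjiang,S13,S49
Cuijianali,"Xinjiang, China",Xinjiang,S49,S66
Dabaiyou,"Xinjiang, China",Xinjiang,S18-2,S49
Daguohuanna,"Xinjiang, China",Xinjiang,S14,S49
Dayoujia,"Xinjiang, China",Xinjiang,S49,S66
Heiyexing,"Xinjiang, China",Xinjiang,S16,S66
Kezimayisang,"Xinjiang, China",Xinjiang,S14a,S66
Kuikepiman,"Xinjiang, China",Xinjiang,S11,S53
Kumaiti,"Xinjiang, China",Xinjiang,S49,S66
Liguangxing,"Xinjiang, China",Xinjiang,S24,S49
Muyage,"Xinjiang, China",Xinjiang,S14,S66
Pinaizi,"Xinjiang, China",Xinjiang,S13,S49
Qiaoerpang,"Xinjiang, China",Xinjiang,S14,S66
Saimaiti,"Xinjiang, China",Xinjiang,S24,S53
Shushangganxing,"Xinjiang, China",Xinjiang,S14,S66
Xinjiangshaxing,"Xinjiang, China",Xinjiang,S8,S102
Xinshisheng,"Xinjiang, China",Xinjiang,S52,S53
Bingtangwei,China,UnclearChina,S17,S25
Haihongzhen,China,UnclearChina,S9,S17
Haiquanhong,China,UnclearChina,S8,S11
Hongxing,China,UnclearChina,S11,
Kuhehonglian,China,UnclearChina,S16,S102
Longjingbaixing,China,UnclearChina,S15,S16
Xiaopuxiangbai,China,UnclearChina,S17,S53
Yinxing,China,UnclearChina,S23,S53
Meiwuming,American,Foreign,S2,S8
99-2,Czech Republic,Foreign,S8,S9
99-12,Czech Republic,Foreign,S24,
99-15,Czech Republic,Foreign,S8,S9
99-27,Czech Republic,Foreign,S52,
99-31,Czech Republic,Foreign,S8,S66
99-37,Czech Republic,Foreign,S17,S18-2
99-38,Czech Republic,Foreign,S11,
99-43,Czech Republic,Foreign,S9,S17
99-44,Czech Republic,Foreign,S24,S9
99-45,Czech Republic,Foreign,S11,
Aurora,Czech Republic,Foreign,S8,S9
Betinka,Czech Republic,Foreign,S8,S52
Hargand,Czech Republic,Foreign,S2,
Jennycot,Czech Republic,Foreign,S2,S9
Jitka,Czech Republic,Foreign,S24,S49
LE5137,Czech Republic,Foreign,S24,
Rumjanaja,Czech Republic,Foreign,S8,S53
Bergeron,France,Foreign,S2,SC
Canino,France,Foreign,S2,S9
Early orange,France,Foreign,S9,S11
Cegledi bibor kajszi,Hungary,Foreign,S14,S66
Cegledi orias,Hungary,Foreign,S14,S66
Cegledi piroska,Hungary,Foreign,S36,
Harmat,Hungary,Foreign,S99,
B088,Italy,Foreign,S54,
B089,Italy,Foreign,S2,S9
B095,Italy,Foreign,S49,S93
Bora,Italy,Foreign,S9,SC
Corlate,Italy,Foreign,S18-1,
Ninfa,Italy,Foreign,S2,SC
Wondercot,Italy,Foreign,S9,S52
Yidalixing,Italy,Foreign,S52,
Pinghexing,Japan,Foreign,S8,S9
Xinzhoudashi,Japan,Foreign,S16,
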