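product,city,level,province
other,Ganzi,5,Sichuan
other,Changping,4,Beijing
rice,Chengdu,4,Sichuan
rice,Meishan,4,Sichuan
rice,Mianyang,4,Sichuan
rice,Ziyang,4,Sichuan
rice,Pingxiang,4,Jiangxi
rice,Hengshui,4,Hebei
rice,Jinhua,4,Zhejiang
rice,Enshi,4,Hubei
other,Changde,4,Hunan
rice,Changde,4,Hunan
other,Zhuzhou,4,Hunan
rice,Zhuzhou,4,Hunan
rice,Xiangtan,4,Hunan
rice,Yiyang,4,Hunan
other,Hengyang,4,Hunan
rice,Hengyang,4,Hunan
rice,Shaoyang,4,Hunan
rice,Chenzhou,4,Hunan
rice,Changsha,4,Hunan
other,Putian,4,Fujian
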