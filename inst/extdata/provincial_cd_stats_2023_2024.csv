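province,product,range,mean,sd,cv
Shanghai,rice,0.16000,0.01260,0.02154,1.70917
Shanghai,wheat_flour,0.03800,0.01363,0.00747,0.54822
Shanghai,other,0.07200,0.00923,0.01430,1.54953
Inner Mongolia,rice,0.11000,0.00291,0.00910,3.12391
Inner Mongolia,wheat_flour,0.04000,0.00975,0.00597,0.61213
Inner Mongolia,other,0.23000,0.00621,0.01315,2.11749
Beijing,rice,0.18000,0.00662,0.01954,2.95102
Beijing,wheat_flour,0.08200,0.01207,0.01003,0.83087
Beijing,other,0.75000,0.02294,0.08647,3.76889
Jilin,rice,0.09800,0.00264,0.00652,2.46670
Jilin,wheat_flour,0.05100,0.00756,0.00718,0.95025
Jilin,other,0.18000,0.00441,0.01315,2.98026
Sichuan,rice,0.58000,0.06715,0.08546,1.27270
Sichuan,wheat_flour,0.08400,0.01887,0.01347,0.71379
Sichuan,other,0.89000,0.02519,0.08833,3.50729
Ningxia,rice,0.04000,0.00249,0.00497,1.99629
Ningxia,wheat_flour,0.04200,0.01061,0.00810,0.76323
Ningxia,other,0.14000,0.00867,0.01898,2.18872
Guangdong,rice,0.52000,0.07912,0.05992,0.75728
Guangdong,wheat_flour,0.10000,0.01387,0.00959,0.69141
Guangdong,other,0.60800,0.04118,0.06208,1.50750
Guangxi,rice,0.60000,0.09311,0.06649,0.71413
Guangxi,wheat_flour,0.03900,0.01527,0.00858,0.56205
Guangxi,other,0.35000,0.04268,0.06159,1.44314
Jiangsu,rice,0.20000,0.01766,0.02129,1.20557
Jiangsu,wheat_flour,0.06600,0.01261,0.01013,0.80349
Jiangsu,other,0.53000,0.01187,0.04428,3.73079
Jiangxi,rice,0.85000,0.11262,0.07652,0.67942
Jiangxi,wheat_flour,0.04000,0.01273,0.00747,0.58670
Jiangxi,other,0.23000,0.06516,0.05304,0.81390
Hebei,rice,0.33000,0.00432,0.01975,4.56663
Hebei,wheat_flour,0.08800,0.00874,0.01034,1.18327
Hebei,other,0.12000,0.00644,0.01194,1.85387
Henan,rice,0.17000,0.01282,0.03040,2.37192
Henan,wheat_flour,0.09600,0.02267,0.01441,0.63551
Henan,other,0.07500,0.00768,0.01188,1.54634
Zhejiang,rice,0.51000,0.03934,0.05523,1.40402
Zhejiang,wheat_flour,0.04200,0.01363,0.00810,0.59409
Zhejiang,other,0.15000,0.01441,0.02382,1.65280
Hubei,rice,0.47000,0.06689,0.05038,0.75318
Hubei,wheat_flour,0.04200,0.01981,0.00818,0.41272
Hubei,other,0.62000,0.02171,0.05397,2.48594
Hunan,rice,0.90000,0.10986,0.10554,0.96069
Hunan,wheat_flour,0.06600,0.01766,0.01058,0.59878
Hunan,other,0.52000,0.10089,0.11111,1.10139
Fujian,rice,0.65000,0.07029,0.07143,1.01620
Fujian,wheat_flour,0.04200,0.01616,0.00609,0.37670
Fujian,other,0.55000,0.03059,0.06568,2.14671
Liaoning,rice,0.20000,0.00836,0.01732,2.07111
Liaoning,wheat_flour,0.04900,0.00867,0.00891,1.02725
Liaoning,other,0.15000,0.00638,0.01165,1.82807
Shaanxi,rice,0.60000,0.04752,0.06668,1.40316
Shaanxi,wheat_flour,0.06200,0.00967,0.00875,0.90467
Shaanxi,other,0.38000,0.01864,0.03265,1.75161
Qinghai,rice,0.07100,0.00648,0.01008,1.55508
Qinghai,wheat_flour,0.05000,0.01045,0.00830,0.79397
Qinghai,other,0.13000,0.01424,0.02562,1.79932
Heilongjiang,rice,0.08200,0.00141,0.00522,3.68673
Heilongjiang,wheat_flour,0.06800,0.00656,0.00823,1.25482
Heilongjiang,other,0.09500,0.00252,0.00887,3.52440
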