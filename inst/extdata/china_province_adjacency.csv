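unit_a,unit_b
Beijing,Tianjin
Beijing,Hebei
Tianjin,Hebei
Hebei,Shanxi
Hebei,Inner Mongolia
Hebei,Liaoning
Hebei,Shandong
Hebei,Henan
Shanxi,Inner Mongolia
Shanxi,Shaanxi
Shanxi,Henan
Inner Mongolia,Liaoning
Inner Mongolia,Jilin
Inner Mongolia,Heilongjiang
Inner Mongolia,Shaanxi
Inner Mongolia,Ningxia
Inner Mongolia,Gansu
Liaoning,Jilin
Jilin,Heilongjiang
Shanghai,Jiangsu
Shanghai,Zhejiang
Jiangsu,Zhejiang
Jiangsu,Anhui
Jiangsu,Shandong
Zhejiang,Anhui
Zhejiang,Fujian
Zhejiang,Jiangxi
Anhui,Jiangxi
Anhui,Shandong
Anhui,Henan
Anhui,Hubei
Fujian,Jiangxi
Fujian,Guangdong
Jiangxi,Hunan
Jiangxi,Guangdong
Jiangxi,Hubei
Shandong,Henan
Henan,Hubei
Henan,Shaanxi
Hubei,Hunan
Hubei,Chongqing
Hubei,Shaanxi
Hunan,Guangdong
Hunan,Guangxi
Hunan,Guizhou
Hunan,Chongqing
Guangdong,Guangxi
Guangdong,Hainan
Guangxi,Hainan
Guangxi,Guizhou
Guangxi,Yunnan
Chongqing,Sichuan
Chongqing,Guizhou
Chongqing,Shaanxi
Sichuan,Guizhou
Sichuan,Yunnan
Sichuan,Tibet
Sichuan,Qinghai
Sichuan,Gansu
Sichuan,Shaanxi
Guizhou,Yunnan
Yunnan,Tibet
Tibet,Qinghai
Tibet,Xinjiang
Shaanxi,Gansu
Shaanxi,Ningxia
Gansu,Qinghai
Gansu,Ningxia
Gansu,Xinjiang
Qinghai,Xinjiang
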