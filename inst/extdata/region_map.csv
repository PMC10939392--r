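province,region,climate_region
Beijing,North,North
Tianjin,North,North
Hebei,North,North
Shanxi,North,North
Inner Mongolia,North,North
Liaoning,Northeast,Northeast
Jilin,Northeast,Northeast
Heilongjiang,Northeast,Northeast
Shanghai,East,East
Jiangsu,East,East
Zhejiang,East,East
Anhui,East,East
Fujian,East,East
Jiangxi,East,East
Shandong,East,East
Henan,Central,Central
Hubei,Central,Central
Hunan,Central,Central
Guangdong,South,Central
Guangxi,South,Central
Hainan,South,Central
Chongqing,Southwest,Southwest
Sichuan,Southwest,Southwest
Guizhou,Southwest,Southwest
Yunnan,Southwest,Southwest
Tibet,Southwest,Southwest
Shaanxi,Northwest,Northwest
Gansu,Northwest,Northwest
Qinghai,Northwest,Northwest
Ningxia,Northwest,Northwest
Xinjiang,Northwest,Northwest
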