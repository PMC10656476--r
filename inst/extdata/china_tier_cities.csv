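city,province,region,tier,ceiling
Beijing,Beijing,east,T1,23000000
Shanghai,Shanghai,east,T1,
Guangzhou,Guangdong,east,T1,
Shenzhen,Guangdong,east,T1,
Chengdu,Sichuan,middle_west,NT1,
Chongqing,Chongqing,middle_west,NT1,
Hangzhou,Zhejiang,east,NT1,
Xian,Shaanxi,middle_west,NT1,
Wuhan,Hubei,middle_west,NT1,
Suzhou,Jiangsu,east,NT1,
Zhengzhou,Henan,middle_west,NT1,
Nanjing,Jiangsu,east,NT1,
Tianjin,Tianjin,east,NT1,
Changsha,Hunan,middle_west,NT1,
Dongguan,Guangdong,east,NT1,
Ningbo,Zhejiang,east,NT1,
Foshan,Guangdong,east,NT1,
Hefei,Anhui,middle_west,NT1,
Qingdao,Shandong,east,NT1,
Kunming,Yunnan,middle_west,T2,
Shenyang,Liaoning,middle_west,T2,
Jinan,Shandong,east,T2,
Wuxi,Jiangsu,east,T2,
Xiamen,Fujian,east,T2,
Fuzhou,Fujian,east,T2,
Wenzhou,Zhejiang,east,T2,
Jinhua,Zhejiang,east,T2,
Haerbin,Heilongjiang,middle_west,T2,
Dalian,Liaoning,middle_west,T2,
Guiyang,Guizhou,middle_west,T2,
Nanning,Guangxi,middle_west,T2,
Quanzhou,Fujian,east,T2,
Shijiazhuang,Hebei,east,T2,
Changchun,Jilin,middle_west,T2,
Nanchang,Jiangxi,middle_west,T2,
Huizhou,Guangdong,east,T2,
Changzhou,Jiangsu,east,T2,
Jiaxing,Zhejiang,east,T2,
Xuzhou,Jiangsu,east,T2,
Nantong,Jiangsu,east,T2,
Taiyuan,Shanxi,middle_west,T2,
Baoding,Hebei,east,T2,
Zhuhai,Guangdong,east,T2,
Zhongshan,Guangdong,east,T2,
Lanzhou,Gansu,middle_west,T2,
Linyi,Shandong,east,T2,
Weifang,Shandong,east,T2,
Yantai,Shandong,east,T2,
Shaoxing,Zhejiang,east,T2,
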