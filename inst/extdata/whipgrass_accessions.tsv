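no	code	origin	latitude	longitude	altitude	group	morphotype	ploidy
1	H041	Dushan, Guizhou	25°20'18"	107°28'41"	930	GZ	II	6x
2	H042	Dushan, Guizhou	25°36'20"	107°29'38"	950	GZ	I	6x
3	H043	Dushan, Guizhou	25°49'23"	107°32'31"	970	GZ	I	6x
4	H044	Dushan, Guizhou	25°34'29"	107°44'13"	820	GZ	II	6x
5	H045	Libo, Guizhou	25°29'58"	107°49'45"	890	GZ	I	6x
6	H046	Libo, Guizhou	25°24'33"	107°53'25"	420	GZ	I	6x
7	H047	Libo, Guizhou	25°15'08"	107°44'35"	410	GZ	I	6x
8	H002	Rongchang, Chongqing	29°24'06"	105°34'59"	600	CQ	II	6x
9	H010	Nanshan, Chongqing	29°33'24"	106°37'56"	420	CQ	II	6x
10	H011	Hechuan, Chongqing	30°04'36"	106°19'32"	270	CQ	II	6x
11	H031	Yuzhong, Chongqing	29°33'13"	106°31'30"	180	CQ	II	6x
12	H035	Liangping, Chongqing	30°46'42"	107°34'46"	400	CQ	II	6x
13	H040	Fuling, Chongqing	29°44'03"	107°22'11"	190	CQ	II	6x
14	H056	Jiangjing, Chongqing	28°49'43"	106°19'50"	350	CQ	II	6x
15	H057	Dazu, Chongqing	29°40'58"	105°30'36"	400	CQ	II	6x
16	Chonggao	Chongqing	-	-	-	CQ	II	6x
17	H001	Leshan, Sichuan	29°14'05"	103°15'36"	500	CDP	II	6x
18	H003	Yaan, Sichuan	30°01'12"	103°02'04"	670	CDP	II	6x
19	H004	Yaan, Sichuan	30°10'46"	103°13'12"	750	CDP	II	6x
20	H006	Hongya, Sichuan	29°53'20"	103°22'31"	540	CDP	II	6x
21	H009	Hongya, Sichuan	29°53'51"	103°22'25"	480	CDP	II	6x
22	H013	Qionglai, Sichuan	30°23'10"	103°27'36"	520	CDP	II	6x
23	H014	Dayi, Sichuan	30°33'56"	103°30'20"	540	CDP	II	4x
24	H016	Meishan, Sichuan	36°25'00"	103°51'12"	465	CDP	I	4x
25	H017	Leshan, Sichuan	29°32'15"	103°49'05"	390	CDP	I	6x
26	H019	Yaan, Sichuan	29°57'26"	103°06'38"	540	CDP	II	6x
27	H054	Leshan, Sichuan	29°06'28"	104°00'27"	340	CDP	II	6x
28	Guangyi	Guangxi	-	-	-	CDP	III	6x
29	Yaan	Yaan, Sichuan	29°59'48"	103°01'33"	620	CDP	III	6x
30	H026	Ningnan, Sichuan	27°30'50"	102°45'25"	1200	YL	II	6x
31	H028	Ningnan, Sichuan	27°08'28"	102°38'36"	1350	YL	II	4x
32	H029	Ningnan, Sichuan	26°54'12"	102°53'56"	710	YL	III	4x
33	H048	Qiaojia, Yunnan	26°53'51"	102°56'46"	920	YL	I	6x
34	H049	Qiaojia, Yunnan	26°56'18"	102°53'45"	680	YL	I	6x
35	H050	Ningnan, Sichuan	26°53'12"	102°54'58"	670	YL	III	6x
36	H051	Ningnan, Sichuan	26°53'32"	102°54'26"	710	YL	II	6x
37	H058	Panzhihua, Sichuan	26°45'07"	101°50'31"	1200	YL	II	6x
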