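"cell_id","group","day","facs","THY1","COL1A1","COL5A2","FN1","VIM","SNAI2","TWIST1","PRRX1","S100A4","DCN","POU5F1","SOX2","NANOG","LIN28A","ZFP42","DPPA4","DNMT3B","TDGF1","SALL4","FOXD3","GDF3","UTF1","TERT","ZIC3","OTX2","STAT3","KLF4","MYC","FGF4","LEFTY2","NODAL","NR0B1","REST","CDH1","EPCAM","ALPL","KRT8","KRT18","CLDN6","EZH2","SUZ12","EED","JARID2","DNMT3A","SETDB1","KDM5B","HELLS","GAPDH"
"cell0001","MRC5",NA,NA,33.0636265162601,28.0672127458054,25.360589031941,26.2325247428755,26.5743029736774,33.2917921254713,30.4991571001284,32.5092761636013,30.7846660110162,31.2265521507737,40,40,40,40,40,40,40,40,40,40,40,40,40,40,40,40,40,28.0276281007927,40,40,40,40,40,40,40,27.6536950321108,40,40,40,40,30.2913439513144,40,31.0959775380664,30.9854015311998,32.8694163849477,32.0421790598811,40,16.6981326033461
"cell0002","MRC5",NA,NA,29.5970177746506,29.3539976096771,25.012613693684,29.5180565378264,25.7262834112187,40,35.5687361777472,33.9005889231477,32.6264768008134,31.5525313326532,40,40,40,40,40,40,40,40,40,40,40,40,40,40,40,40,30.7468950341955,33.7364510406766,40,40,40,40,40,40,40,40,40,40,40,40,40,33.6953573470725,40,40,40,40,33.66841715003,19.0664936413996
"cell0003","MRC5",NA,NA,27.4157182547426,26.5501810202396,28.6052279075213,28.5576415476816,20.7223735215466,31.0030528722364,27.0752529652087,25.8497662608635,25.3812978574114,30.8494229371487,40,30.2869119465834,40,40,40,40,40,40,40,37.8951317164456,40,40,40,40,40,26.0224645493081,40,28.2419905336151,40,40,40,38.2492862879209,40,40,40,40,40,40,40,31.2953833607813,30.2375642311855,40,40,27.1882000941494,28.8147743810714,40,40,16.5024507124601
"cell0004","OSKM",8,"TRA160",30.4534735626665,40,40,30.4589083295233,40,40,40,40,40,40,34.5379604426436,40,40,35.6121905299047,40,40,32.6341861556774,34.9498020044265,40,37.9783788873337,40,33.0807187296922,37.4436890879369,40,33.7771812727076,40,29.7782452398796,30.7461807140087,40,40,40,40,40,30.9575153883674,31.1728980326793,40,33.5822602278893,32.6584241335399,32.2859984185738,34.3240878194266,31.5660215113369,31.8844595748848,34.7286048555988,32.0926369781022,30.8273895775109,32.5459562710805,30.0513648676621,18.9934647099349
"cell0005","OSKM",4,"SSEA4",30.0418765256176,40,32.8573639027977,28.9441974058767,26.7859534628658,31.9984242609295,34.3167858113297,26.0256130116179,30.4677578453401,30.5444735448177,40,40,40,40,40,40,32.2594149053824,40,40,40,40,40,40,40,40,31.5482633250492,40,27.824889762239,40,40,40,40,40,40,40,40,40,40,40,27.1491351461047,31.8041297079913,31.6789450039701,29.6305399530767,40,40,33.5170259507284,40,17.8897103054816
"cell0006","OSKM",14,"TRA160",40,40,40,40,28.8152256679376,40,40,40,40,40,32.0520429205363,40,40,40,31.3303058979752,40,31.7272318309799,29.3143274947609,40,40,40,40,31.9189754813625,33.7770732669265,30.7778120661337,32.3109758837397,30.3132127364298,27.4166581883855,33.9393120464551,31.8395456039407,40,40,40,34.5242130863484,29.6037462818953,30.5889115440641,31.6510957145755,28.5659425577172,34.1090896225159,31.0087264447846,31.4805221635336,27.6876660639822,33.4485190033425,34.3596432885752,40,31.1216732129817,31.069447026422,17.3869402632951
"cell0007","OSKM",14,"TRA160",40,40,40,29.5442824019525,40,40,40,40,34.3478419979927,40,32.8541114794414,40,33.6683464787386,32.4300690043364,35.6642589627528,34.3165618838118,33.4636401901529,33.0175000619342,30.3700710400068,35.7370120866326,30.5672437886711,32.0006739242582,36.4591907139085,30.7762308937425,31.0702872751947,29.6833381100471,40,32.4666261155279,36.5107470541216,39.1715782301505,34.6224414441903,40,40,32.7646892620631,29.7513080789748,30.7421916413973,40,40,40,34.2837740138837,33.139117144848,32.8678914750522,33.423772817404,34.1675424072529,30.2881545956323,33.8961170528474,31.2125299550015,18.2295610699071
"cell0008","OSKM",8,"TRA160",40,40,40,27.0339858671015,40,40,40,40,40,40,32.0561029777912,40,32.7708690231904,40,40,40,35.0146340757092,35.0509782951358,34.1611368033614,40,40,36.4821391461948,40,40,32.4995459913628,25.9991130226947,31.5478196548131,31.1460747095586,40,40,40,40,40,40,40,34.1068242168756,36.9590637813043,40,40,31.7474139433088,28.6537607774879,28.5434854933556,32.1454688955033,27.5929397784598,34.9523365881837,35.4751192081025,30.2780857606306,18.3333654017215
"cell0009","OSKM",14,"TRA160",40,40,40,40,40,40,40,40,40,40,30.1316596415784,32.7887945888462,35.8586604548134,40,34.6485563244842,34.8069287344122,36.0672003909885,30.4462405056444,33.6396165375808,37.5147370404031,35.4070273760136,32.319448088903,37.2442014265543,32.5888950172476,34.2193159167141,34.4926896525315,30.7690845937024,30.2968488631588,33.5005005717368,31.7954435078977,33.5532863778082,40,40,32.8792934355169,35.3596081568014,32.8961395069661,40,40,40,33.0793098440816,32.453996560472,33.5015764189268,31.6526298536339,31.2865552290763,33.7429619664394,30.9905734727062,33.2171843753624,18.5336248209753
"cell0010","OSKM",14,"TRA160",28.8469712692227,40,40,26.020792662879,40,40,31.3576345880749,40,40,40,40,29.7672826037224,40,40,40,40,40,31.0861148769488,40,40,40,40,40,40,40,40,40,40,40,40,40,40,40,31.6098542996595,40,30.7239388993145,40,40,40,40,40,40,40,40,40,40,40,17.0684867746736
"cell0011","OSKM",4,"SSEA4",25.6586066821766,40,25.4876357513291,40,40,40,40,33.2356422587068,40,40,40,40,40,40,40,40,40,40,34.9118069002375,40,40,40,40,40,40,40,40,40,40,40,40,40,40,40,40,40,30.6567320911256,40,40,40,40,40,40,40,40,40,40,16.1999313127542
"cell0012","H9",NA,NA,40,40,40,40,40,40,40,40,40,40,30.8488414306917,30.2065957119354,29.8636250911256,31.7696245162894,35.1046783939941,36.4742962007087,27.2826502516785,30.9865136095034,28.2666568055925,39.9,40,30.6474109110356,32.1568076126922,31.8622840231794,29.971548299146,26.3538095706416,31.3488517125728,28.1057571595348,29.7764703080372,33.4253718870799,30.6457839796074,40,40,40,28.285392936945,32.5336353309221,40,40,40,28.7020598125299,31.0690188552991,29.2040162558148,31.4892996274515,31.6544523446446,31.5115560736265,32.2111151477822,30.3237560717144,16.9112010721065
"cell0013","H9",NA,NA,32.7058908646524,40,40,40,40,40,40,40,40,40,31.5835511708759,34.1025757956405,33.6127481459412,36.9927225809841,34.4128313335828,34.1032830949818,31.9778109680005,37.5792240079808,34.7449431323711,33.2397339839986,34.8412221063273,40,39.3416782566827,33.4214939753496,37.6686886004348,33.8124424401211,28.3949455114074,33.117779585095,39.9,36.7330735737043,37.266309087878,40,40,35.3303804748613,36.4599010696313,34.7166246846151,40,33.6969598296606,40,34.0585161279639,40,31.3718742454671,33.5388661396942,36.3545905522387,29.6760897510455,40,34.8353356494449,20.0917800838756
"cell0014","H9",NA,NA,40,40,40,40,40,36.387222373113,40,40,40,40,30.2092156405961,37.4177405702616,37.4274751213782,35.4389886966225,33.0660189756801,35.9868465997906,37.0940849400094,32.2325069028581,34.4118233543794,40,34.5559974364763,38.3523159208553,38.603214167968,36.6899288524392,35.5042246552636,27.7968258208933,29.5765263913152,30.1238663836138,37.5011921459889,35.0781408594036,34.808003461485,40,40,28.6278810512759,34.4759794124895,33.9346261236519,40,40,40,32.9837798870252,34.2190939866742,34.6017580609162,31.1630107026535,34.5898115681615,31.4417676612603,34.6486828865288,32.9836999538396,19.4617624104174
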