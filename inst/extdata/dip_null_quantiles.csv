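"n","p0","p0.01","p0.02","p0.05","p0.1","p0.2","p0.3","p0.4","p0.5","p0.6","p0.7","p0.8","p0.9","p0.95","p0.98","p0.99","p0.995","p0.999","p1"
4,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125
5,0.1,0.1,0.1,0.1,0.1,0.1,0.1,0.1,0.1,0.1,0.1,0.1098797,0.1368735,0.1553498,0.172374,0.1808015,0.1863562,0.1937692,0.1970739
6,0.08333333,0.08333333,0.08333333,0.08333333,0.08333333,0.08333333,0.08333333,0.08333333,0.09140473,0.1015503,0.1123435,0.1248237,0.1399338,0.1494008,0.1578532,0.1613049,0.1633803,0.1661352,0.1666543
7,0.07142857,0.07142857,0.07142857,0.07142857,0.07142857,0.07324178,0.08253284,0.09069885,0.09860601,0.1060617,0.1136823,0.1217941,0.131232,0.1369161,0.1415323,0.146456,0.1574531,0.1794396,0.194124
8,0.0625,0.0625,0.0625,0.0625,0.0675884,0.07759157,0.08506249,0.09152947,0.09751635,0.1030977,0.1088416,0.1144655,0.1208012,0.1248904,0.1387689,0.1477385,0.1550329,0.1660615,0.1831357
10,0.05,0.05310153,0.05688483,0.06302465,0.06876339,0.07634143,0.08140359,0.08549286,0.08936145,0.09280158,0.0962124,0.0996498,0.1112849,0.1211526,0.1302393,0.1365108,0.1420433,0.1542047,0.1673299
12,0.04166667,0.05265197,0.05561704,0.06106313,0.06583478,0.07124841,0.07516219,0.07819637,0.08073659,0.0830126,0.08832983,0.09519807,0.1042857,0.1113493,0.1196458,0.1249687,0.1303347,0.1422394,0.1629334
15,0.03507825,0.05056587,0.05319675,0.0568722,0.06013674,0.06378548,0.06620483,0.06985757,0.0738613,0.07785064,0.08227348,0.08752466,0.09492404,0.1018476,0.1099611,0.1152013,0.1203996,0.1301655,0.1551365
20,0.03532197,0.04523573,0.04669932,0.04901856,0.05186125,0.05649928,0.05998406,0.06299828,0.06594484,0.06892489,0.07237752,0.07700654,0.08394636,0.08958793,0.09676017,0.1021481,0.106682,0.1158133,0.1290419
25,0.03125521,0.03988452,0.04159731,0.04485319,0.04779439,0.05161974,0.05431896,0.05680663,0.05944948,0.06266331,0.06596583,0.07004437,0.07602744,0.08132303,0.08749797,0.0924263,0.09676207,0.1065975,0.1223092
30,0.03027197,0.03725384,0.03897921,0.04147712,0.04388754,0.04710036,0.0497528,0.05249584,0.05496094,0.05757903,0.06048174,0.06409243,0.07007025,0.07516824,0.08102436,0.08565909,0.0893433,0.09939066,0.1065457
40,0.02563336,0.03271516,0.03398168,0.036186,0.03847611,0.04152488,0.04389553,0.04605811,0.04826998,0.05069739,0.05333308,0.05651419,0.06130627,0.06564603,0.07080011,0.07414199,0.07784663,0.08588965,0.09460879
50,0.02395181,0.02928842,0.0305719,0.03262527,0.03464482,0.03740032,0.03954646,0.04152391,0.04347753,0.04564326,0.04789369,0.05093162,0.05547802,0.05943984,0.06406214,0.06723747,0.06991529,0.07702422,0.09371996
75,0.01897621,0.02466697,0.02566753,0.02739915,0.02903361,0.03119106,0.03297794,0.03456382,0.0361473,0.03781389,0.03975383,0.0422335,0.04595867,0.04922154,0.05323519,0.05596848,0.05845972,0.06384892,0.06969066
100,0.01763798,0.02142459,0.02231807,0.02386167,0.02528572,0.02725889,0.02875979,0.03015939,0.03154327,0.03297558,0.03466262,0.03680134,0.04005353,0.04272213,0.04623336,0.04878686,0.05089371,0.05537821,0.0639588
150,0.01448247,0.01775148,0.01857324,0.01971933,0.02085743,0.02243204,0.02373502,0.02485642,0.02602263,0.0272236,0.02858484,0.0303529,0.03292559,0.03530209,0.03804922,0.03978458,0.04146291,0.04530298,0.05468719
200,0.0126635,0.01557308,0.01615614,0.01721731,0.01820677,0.01955673,0.02060005,0.02162716,0.02258925,0.02365923,0.02485962,0.02637243,0.02854762,0.03058372,0.03314428,0.03449766,0.03632679,0.04004649,0.04649987
300,0.009858771,0.01272166,0.01330463,0.01415848,0.01499575,0.016115,0.01698866,0.01780295,0.01861086,0.01947794,0.02045167,0.02171688,0.02356853,0.02520716,0.0272619,0.02877774,0.03012,0.03308296,0.03927478
500,0.007100271,0.009961051,0.01036548,0.01103042,0.01171389,0.01257049,0.01324351,0.01384885,0.01446814,0.01517178,0.01594494,0.016881,0.01827889,0.01954769,0.02111892,0.02223825,0.02343601,0.02549616,0.02817843
750,0.006487376,0.008188502,0.008541289,0.009072435,0.009618078,0.01030872,0.01086714,0.01139154,0.01191978,0.01246865,0.01308309,0.01384748,0.01501177,0.01603916,0.01731486,0.01823331,0.01911794,0.02056701,0.0238377
1000,0.005870029,0.007144729,0.007418132,0.007892282,0.008346783,0.008935961,0.009410002,0.009869736,0.01031578,0.01078093,0.01131818,0.01201002,0.01300028,0.01390816,0.01503055,0.01564486,0.01629597,0.01747348,0.01997813
1500,0.00470072,0.005860965,0.006136574,0.006481604,0.006833801,0.007328413,0.007714558,0.008089389,0.008442796,0.008839562,0.00928063,0.009823733,0.01064357,0.01136769,0.01223502,0.01291319,0.01348444,0.01460963,0.01887916
2000,0.004326526,0.005038348,0.005255876,0.005600802,0.00593725,0.006368859,0.006716248,0.007036637,0.007346087,0.007676156,0.008039541,0.008535771,0.009208734,0.009836131,0.01066082,0.0111577,0.01165782,0.01262295,0.01494591
3000,0.00350379,0.004147604,0.00432903,0.0046089,0.004866623,0.005205767,0.005477659,0.005737706,0.005992711,0.00626819,0.006583958,0.006985481,0.007591564,0.008114944,0.00881059,0.009231649,0.009572785,0.01041867,0.01158674
5000,0.002630778,0.003216051,0.003358133,0.003579889,0.003781886,0.004047848,0.004275654,0.00446066,0.004660636,0.004867874,0.005119743,0.005425259,0.005852392,0.006260113,0.00677243,0.007096406,0.007452248,0.00805694,0.009023852
7500,0.002234555,0.002629731,0.002731694,0.002916848,0.003072604,0.003302316,0.003475456,0.003639661,0.003807954,0.003986619,0.004180259,0.004432196,0.004792356,0.00514688,0.00554643,0.005817286,0.006102889,0.006564032,0.007162429
10000,0.001956577,0.002316839,0.002389148,0.002532936,0.002681231,0.002873443,0.003024911,0.003159987,0.003301606,0.003455516,0.003626579,0.003843349,0.004169848,0.0044693,0.004783007,0.004997687,0.005194112,0.005618565,0.006427952
15000,0.00148407,0.001874529,0.001944263,0.002062582,0.002175886,0.002337989,0.002461658,0.002577513,0.002691593,0.002814785,0.002946311,0.003114798,0.003375003,0.003612635,0.0038868,0.004102695,0.004263658,0.004670903,0.005424492
20000,0.001335001,0.001635618,0.001692891,0.001784331,0.001887937,0.002025292,0.002129416,0.002232123,0.002337058,0.002441849,0.0025584,0.002705629,0.002930305,0.00314054,0.003367549,0.003511283,0.003722029,0.004169584,0.004734799
30000,0.001045461,0.00133183,0.001383114,0.001466925,0.001550601,0.001661898,0.001749325,0.001825838,0.001907413,0.001994665,0.002093049,0.002211471,0.002399794,0.002561846,0.002732361,0.002846209,0.002963238,0.003161347,0.003777545
50000,0.0008387674,0.001024048,0.001068724,0.0011384,0.001203301,0.001289854,0.001359405,0.001424452,0.001486682,0.001552121,0.001632079,0.001726792,0.001870593,0.001996926,0.002145195,0.002228778,0.002325968,0.002511031,0.002891684
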