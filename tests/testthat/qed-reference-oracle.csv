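mw,alogp,hba,hbd,psa,rotb,arom,alerts,qed_unweighted,qed_maxinfo
218.7393731,3.678319627,5,0,32.67351365,1,1,2,0.630555340607,0.530583677094
337.2814312,0.7272072774,2,1,80.97435362,3,1,0,0.879342135767,0.882110727212
276.1911141,7.069861555,4,0,11.7485274,3,1,1,0.515049889298,0.546497826627
704.1499367,4.537206317,3,5,145.8102578,5,1,1,0.331313966329,0.287377173633
384.0809179,3.91811679,6,3,24.04765619,5,1,1,0.662177571105,0.666175491
508.4719368,6.34426122,3,3,162.4641685,3,0,0,0.371641955742,0.405656555378
224.7896237,2.702568618,5,4,10.23429369,3,3,0,0.521980834452,0.54365523339
559.3784613,-0.3194788703,6,1,50.96290928,6,3,1,0.457995612656,0.418607302666
263.5141355,0.01698876365,7,1,132.5121306,10,1,1,0.522323808022,0.588009325843
335.051909,3.50000758,4,3,52.45958485,5,2,0,0.819204870039,0.782929577436
304.3848822,0.3940378557,5,4,21.36373716,5,2,1,0.616426073185,0.598425194623
499.9333506,1.538274113,6,3,85.32701571,6,1,0,0.576730684253,0.550474554261
365.347184,3.629431402,2,7,94.82654036,2,0,1,0.447099814595,0.38074919416
407.1470763,4.710348031,3,3,45.11377514,3,2,1,0.716016392484,0.646374206494
1008.383815,2.829691072,3,3,106.7992405,4,0,1,0.454243796545,0.378080003216
304.3963631,3.417854039,4,1,112.3886207,2,2,0,0.869136666433,0.915216459557
595.9516742,5.596521379,6,2,103.7639582,2,2,1,0.463151498291,0.438496259244
400.9589987,1.498431517,4,4,119.8115939,2,0,1,0.548981902175,0.524683714284
483.3074794,2.583994078,4,4,103.7211473,3,2,0,0.586927909165,0.539128370759
524.0587455,0.9952637638,6,4,48.72775478,4,1,1,0.500886420213,0.441882672184
147.2905551,1.195461477,0,0,39.88433689,4,3,0,0.392234104019,0.531785081418
310.9439536,4.906214633,2,2,89.64887928,5,4,0,0.54080658859,0.548238668934
306.3215246,1.077326249,9,3,88.58594295,4,1,0,0.602301946919,0.755679537298
242.0498539,0.2355050357,3,2,27.66394751,4,1,0,0.797364501472,0.791372776014
448.2693445,3.652511648,4,2,62.19588768,4,4,2,0.451189722307,0.369821048376
363.359008,3.410747975,5,1,134.3330013,1,1,0,0.735363891466,0.815481186521
385.2644099,2.111514255,3,2,98.19997212,2,3,0,0.71213651916,0.706994083059
263.0160404,5.482273575,2,0,87.03720589,2,1,0,0.711250574017,0.706204627217
385.3197547,4.947437574,4,2,174.4800565,3,2,0,0.61870871179,0.760269210375
136.6791804,5.86703778,1,2,71.9076675,5,3,1,0.404452680074,0.423390307874
545.1034251,0.9115034351,4,1,60.19013955,3,2,1,0.668003616222,0.583804409644
587.7487375,3.58515708,3,1,31.37948935,2,2,0,0.659238215987,0.583293512734
993.449885,0.6703443178,6,1,76.13943446,4,2,0,0.533582996759,0.486732190885
98.32719636,4.02086249,5,0,60.43546526,4,0,1,0.56579307596,0.496856557218
445.2517543,2.850202185,4,3,173.6585712,3,4,3,0.281397151614,0.249954951939
949.2852724,-1.169907144,4,1,53.09561643,3,0,0,0.451087506538,0.388613157924
353.3021907,4.095154143,3,0,26.51297334,6,0,0,0.735695004953,0.719414926094
673.909519,-0.3082796403,5,3,123.4051919,3,1,0,0.432067785,0.406787918997
301.9054764,1.666975166,7,1,52.51404263,8,4,1,0.476032291812,0.496786896478
596.5467188,1.231656403,0,5,84.35587769,4,2,0,0.291295067204,0.352333941485
353.7297661,1.139904069,4,1,15.60108135,7,2,0,0.774720573551,0.802607019235
198.8393637,-0.05528166132,6,3,108.5874562,2,1,0,0.588439141402,0.614999670719
365.6453189,-3.18719487,3,1,92.74150162,5,2,1,0.573900115134,0.566087780035
276.3938045,2.604412715,1,0,29.03357818,6,1,1,0.663492561678,0.734296905932
352.1347165,0.9533117967,4,2,228.1053975,4,2,2,0.493199603456,0.603949070281
286.5258556,1.527818182,3,4,58.41537735,5,0,0,0.672526978501,0.619825604386
194.9373717,2.500493921,6,1,47.79980253,4,5,0,0.463237957571,0.474819646395
476.5572585,3.068923021,3,1,102.3253634,8,2,0,0.682281758469,0.633380775971
337.1506533,3.014994601,5,4,103.3919121,3,1,0,0.678082560486,0.678830079646
407.4542274,-0.9043464945,4,2,51.74670525,2,1,1,0.667952730605,0.624180314512
272.7061298,2.954721267,6,5,53.569749,4,1,0,0.605242952719,0.581080982468
347.8777364,-0.5959850748,4,2,34.40330697,4,2,0,0.772660269059,0.774227508414
176.7735136,1.611199893,4,1,9.497408866,1,2,0,0.684768463161,0.707243334857
761.6756048,1.927504277,5,2,45.65562733,3,2,0,0.578200443852,0.501692868073
260.4520507,2.794316797,7,1,74.26087718,4,0,0,0.748639033103,0.832643363518
442.9939117,5.161030579,9,1,17.73378469,6,1,0,0.500986324153,0.637314337395
492.6694933,1.027343391,6,0,97.8666642,1,2,0,0.598362612161,0.5898120676
175.5282063,1.893875881,4,2,17.57580998,7,1,0,0.675156908978,0.658709728696
260.1156459,1.222146769,5,3,45.2625175,2,1,2,0.65284222725,0.551019951205
257.9633516,0.8712202381,2,1,72.5928891,2,0,0,0.808349830481,0.797549356831
570.3359499,3.246866051,3,2,93.55876239,2,1,2,0.546189902482,0.422747212724
227.2579712,0.4643151218,7,1,44.291634,8,0,0,0.6124109792,0.646055097177
281.4437473,3.012172675,4,7,98.28648976,4,2,1,0.503560372322,0.438156130729
304.1894487,0.2616715193,2,4,133.9590494,4,0,1,0.545212114074,0.554454309609
212.4938203,0.9679444082,5,0,60.73749893,3,1,0,0.765579103796,0.747059378745
183.3039603,0.3020055376,6,4,19.02745835,5,2,0,0.528646409718,0.530635769476
657.7661853,3.760261305,5,4,77.8219638,6,1,0,0.450751422965,0.37528989988
319.5266088,2.106890094,8,1,81.95576629,7,2,0,0.710622527654,0.830661592965
635.6079567,2.500749098,2,3,68.03109379,8,3,1,0.422442695273,0.333548643092
655.1416324,2.397542012,3,4,58.38133242,7,1,0,0.464756055167,0.365672814129
325.5113232,4.378185983,6,2,16.67178375,2,2,0,0.75903240634,0.846383925678
336.1082347,4.672042395,1,1,126.584504,3,1,0,0.665047559446,0.845240346658
359.3884891,1.577761296,3,4,79.7709743,7,1,1,0.634469748588,0.558284640392
302.2780488,-0.1122821062,9,0,139.299689,7,1,0,0.486904978654,0.673987380365
452.3858933,1.638862265,5,1,22.09086411,5,2,3,0.552726680939,0.422257159416
646.7927348,-0.6870603815,4,3,91.86931508,3,0,0,0.432867925056,0.379200846927
206.3086951,2.975133913,4,0,31.21024148,2,0,0,0.722057126245,0.694756579569
418.5792964,0.7385138665,3,3,140.1910493,4,0,2,0.502511413744,0.457871277522
226.0697609,0.7114711453,5,2,30.31466651,6,0,0,0.697102314911,0.696045232871
144.6095277,2.705016027,2,5,142.9875671,1,0,0,0.404742980985,0.385621973502
573.0744245,6.732438963,1,1,30.1804849,5,0,1,0.350452123075,0.363740240297
260.2156893,2.319255477,2,1,50.57275826,4,0,0,0.858676004247,0.842883584282
173.3607898,5.667678967,2,1,84.62246906,6,0,0,0.58734724104,0.560888978912
223.5227167,2.441020008,6,4,94.83835461,7,0,1,0.521433313318,0.49531600852
492.4284658,2.046353765,1,4,67.20496502,2,2,0,0.503671817908,0.509755421479
118.987875,2.131526838,4,0,25.21783386,3,0,0,0.610930873531,0.567620892397
336.3069385,2.111178379,6,1,96.42670497,4,1,0,0.831620733306,0.904431838195
259.2725184,2.244481427,5,1,108.6682881,7,1,1,0.749544986586,0.755018197353
327.9327594,4.303714864,3,2,41.33118287,9,0,1,0.686022701789,0.620153074502
265.1903258,0.1505790938,3,1,166.1858564,5,0,1,0.601343451139,0.699365836648
299.8502015,2.902189731,2,1,71.73450818,2,1,1,0.889906883798,0.852886280767
354.5603232,-0.09001781238,4,0,52.11163907,7,5,0,0.425826550032,0.409896566011
823.3248226,1.288194211,2,2,36.58356033,4,1,0,0.56719469679,0.481437823971
229.212283,1.376167866,3,1,125.3286515,4,0,0,0.738652434938,0.781618144839
414.6530065,2.54292872,3,1,81.27579206,1,0,0,0.752763322903,0.715781695626
330.582111,2.423957735,3,3,141.3388054,5,1,0,0.705052018288,0.762577181278
179.6669282,-1.107159305,2,2,82.32032333,1,2,0,0.615489541435,0.582425448317
638.7106823,2.161581933,7,9,20.2669726,7,0,0,0.245759482835,0.210706244379
283.6199854,0.4191622189,5,3,69.89816133,5,0,0,0.689230291351,0.682128453624
266.1569975,5.444643205,1,1,119.9241451,6,3,0,0.505175745837,0.62656090051
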