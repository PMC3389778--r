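"state","value"
"V",-86.7013722029288
"m",0.00116324601708514
"h",0.98967336095862
"j",0.993319935032334
"xr",0.000167653160100477
"xs1",0.00547780288223621
"xs2",0.0226400865400127
"xto",0.000294227395853394
"yto",0.321021338314841
"z01",0.935844127019363
"z02",2.182214853954e-05
"z03",0.000156145704316991
"z04",0.0250411155885634
"z05",5.0613372849321e-06
"z06",1.18020993990201e-10
"z07",8.44484730339972e-10
"z08",1.35430172982379e-07
"z09",9.12443076919121e-12
"z10",2.12792904155924e-16
"z11",1.52246387941829e-15
"z12",2.44149557541818e-13
"z13",5.41913395219388e-18
"z14",1.94788185360699e-20
"z15",3.48379494086476e-20
"z16",1.47761996102948e-19
"z17",1.45352902469897e-20
"z18",2.53405536586159e-18
"z19",4.31265668955033e-18
"z20",3.52808069682287e-19
"z21",0.0375684809182893
"z22",8.2563131577755e-06
"z23",0.000101723169642192
"z24",0.00125299183786216
"z25",2.03182076797961e-07
"z26",4.4652719849987e-11
"z27",5.50150667649578e-10
"z28",6.7765711491068e-09
"z29",3.66290708395901e-13
"z30",8.05001872228435e-17
"z31",9.91806236386429e-16
"z32",1.2216605350875e-14
"z33",2.20901877063479e-19
"z34",1.11354337292605e-21
"z35",7.69648749828789e-21
"z36",8.01785846648828e-21
"z37",9.9229412280226e-20
"z38",1.36573940112099e-19
"z39",8.96608051264541e-19
"z40",8.5413654665253e-20
"cai",0.000344407890214138
"cansr",0.464321859955734
"nai",6.74096685682001
"ki",140.087498473195
"ltrpn_ca",0.0198546345791712
"htrpn_ca",0.13867729068261
"cmdn_ca",0.00632384943556454
"csqn_ca",0.0714518719816873
"xb_n0",0.750403148043822
"xb_n1",0.0316999236912437
"xb_p0",0.0853671361596293
"xb_p1",0.0232751765211643
"xb_p2",0.0475175147619163
"xb_p3",0.0617371008222595
"atpi",7.99175793568546
"crp",21.6500498866737
"cam",3.90351643488878e-05
"nam",1.98699755679605
"nadh",0.409587734572353
"adpm",0.00369835346853809
"dpsi",167.468007379198
"cit",0.0131609449025157
"isoc",0.00586860621889181
"akg",0.000655897237965079
"scoa",0.420962746176406
"suc",0.00247849610721035
"fum",0.00190253499227273
"mal",0.00176920114006304
"oaa",0.000201573224812566
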