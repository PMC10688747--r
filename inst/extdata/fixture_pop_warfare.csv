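"year","N","W","C"
250,0.0499178058348117,0.497164725635992,35.4941847570307
275,0.0678289699189758,0.479003737948175,36.4360917837575
300,0.0926389510328512,0.466864430501689,34.7433647572219
325,0.124218041377604,0.439180079896578,39.2233657309082
350,0.163049385721108,0.434841162904953,39.7695112370834
375,0.213746501308239,0.422901812330712,37.4464848677835
400,0.278409838513658,0.419445249597333,38.7270176200552
425,0.352585963475862,0.410853784565253,40.3535933883543
450,0.429843024897988,0.414470805487864,41.2647499546518
475,0.519098394024417,0.419282060248493,39.8788678345462
500,0.599601107669244,0.427461326524326,43.131369071919
525,0.668908563419896,0.449639765307237,43.0407190249226
550,0.740563595092064,0.469558230219755,40.5415978266378
575,0.781476472545106,0.495921550013422,34.7179985320842
600,0.841816941775486,0.545593079910057,38.0742330292108
625,0.874578731283406,0.585438877583318,37.9515457617321
650,0.872233404325726,0.62613585356369,37.9223799779482
675,0.87670809767234,0.688910452483069,40.2031108880033
700,0.8956955435408,0.743086884186695,41.733419578638
725,0.890005991532453,0.809460020665433,42.4120988338325
750,0.910511732190796,0.872162883807115,43.7352247589257
775,0.884128016453164,0.943455510653452,44.4653069288951
800,0.884632666349108,1.00161295990797,43.3512015031925
825,0.871767702819926,1.08751653384426,37.5065171324819
850,0.857042068649664,1.17961734643041,39.0927955009329
875,0.855115766752135,1.31249487143468,38.7395274258767
900,0.827242749530642,1.41003570008893,28.2177127246086
925,0.842182401934296,1.60745474733696,24.6443644583286
950,0.814646000955861,1.86162475888125,24.1679314344022
975,0.808785272373477,2.19540421366835,25.937404892001
1000,0.767879065661729,2.45041958455098,29.6107548372705
1025,0.728503613187602,2.72605825579513,29.0419133241932
1050,0.706605705960644,3.07521757821841,29.7639425270971
1075,0.663576459844051,3.30065372696035,29.2820219242787
1100,0.628859143231915,3.61755771856067,25.7206746030343
1125,0.604999350999145,3.98482277338822,25.1805527305082
1150,0.564940918621221,4.37961214545969,24.7981462955017
1175,0.529998879300622,4.78107642519764,25.2961648842945
1200,0.491955226887366,5.19713665802561,28.4769928001969
1225,0.4508419776008,5.44647609876858,30.2132160364557
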