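"year","N","W","C"
50,0.0498032431742493,2.01225190178467,35.4941847570307
75,0.110055578794555,1.7433053597921,36.4360917837575
100,0.236212291807377,1.55326027933529,34.7433647572219
125,0.438018098122969,1.43548964991281,39.2233657309082
150,0.726867372872421,1.37436208741989,39.7695112370834
175,0.95369438356834,1.41499295083541,37.4464848677835
200,1.00427154356087,1.50510941595276,38.7270176200552
225,1.02936196617498,1.61057996320271,40.3535933883543
250,1.04537583004953,1.75583898463405,41.2647499546518
275,1.06282567405497,1.9403354126144,39.8788678345462
300,1.05376910141604,2.15886654021755,43.131369071919
325,1.10897899208665,2.32816201431199,43.0407190249226
350,1.1018225288948,2.66050215550884,40.5415978266378
375,1.07201840779638,2.9408055324768,34.7179985320842
400,0.974989057571479,3.18158619419898,38.0742330292108
425,1.0033040582507,3.35424607087639,37.9515457617321
450,1.01699168336559,3.63521374826235,37.9223799779482
475,1.00224366612109,3.91194197207688,40.2031108880033
500,1.06405674171013,4.21848278091893,41.733419578638
525,1.09910016117004,4.7289185868204,42.4120988338325
550,1.08717736552344,5.25079677171346,43.7352247589257
575,1.10246588775278,5.85299942011721,44.4653069288951
600,1.1340307425234,6.6624625028109,43.3512015031925
625,1.1079310133076,7.42704568835873,37.5065171324819
650,1.04031154513804,7.99398280836737,27.0927955009329
675,0.861541534350799,8.307996897732,26.7395274258767
700,0.835768757523737,8.24856383201958,26.2177127246086
725,0.815295948157164,8.23527591440501,22.6443644583286
750,0.762707381618156,8.00885817925676,22.1679314344022
775,0.750010828206663,7.76420643020316,23.937404892001
800,0.748115457724899,7.42953102545889,27.6107548372705
825,0.821804656524816,7.38125374010755,27.0419133241932
850,0.820449666228824,7.24966110555312,27.7639425270971
875,0.849238130828665,7.38955757790651,27.2820219242787
900,0.83240976071732,7.27822817064597,23.7206746030343
925,0.779124597096668,7.15203555469838,23.1805527305082
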