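"calBP","yearAD","SPDn","SPDnn","Rn","Rnn","LithPct","War","Rwar"
1900,50,0.0498032431742493,0.0569865800466728,NA,NA,35.4941847570307,2.01225190178467,NA
1875,75,0.110055578794555,0.126873314902105,0.792905394068309,0.800373265811035,36.4360917837575,1.7433053597921,-0.14347150082321
1850,100,0.236212291807377,0.272972507286811,0.763745442277902,0.766182016056572,34.7433647572219,1.55326027933529,-0.115426815378989
1825,125,0.438018098122969,0.494272338398289,0.617529287201003,0.593715573381715,39.2233657309082,1.43548964991281,-0.0788501174317321
1800,150,0.726867372872421,0.836602201886546,0.506483800740819,0.526262033364883,39.7695112370834,1.37436208741989,-0.0435163234160645
1775,175,0.95369438356834,1.10098777100585,0.271599237291607,0.274614338539757,37.4464848677835,1.41499295083541,0.0291348622961911
1750,200,1.00427154356087,1.15503922256651,0.0516744579268306,0.0479265518203248,38.7270176200552,1.50510941595276,0.0617410478469126
1725,225,1.02936196617498,1.17437664289127,0.0246767135719962,0.016603187804871,40.3535933883543,1.61057996320271,0.0677287425345115
1700,250,1.04537583004953,1.23475269791769,0.0154373067526961,0.0501332152931756,41.2647499546518,1.75583898463405,0.0863524568865361
1675,275,1.06282567405497,1.22922036083015,0.016554624867324,-0.00449058999627605,39.8788678345462,1.9403354126144,0.0999140546221634
1650,300,1.05376910141604,1.21247774317484,-0.00855773435254409,-0.0137141279144115,43.131369071919,2.15886654021755,0.106722482836225
1625,325,1.10897899208665,1.2780479898319,0.0510664078200272,0.0526679184629526,43.0407190249226,2.32816201431199,0.0754957871569062
1600,350,1.1018225288948,1.26354859046567,-0.00647411187329545,-0.0114098018363137,40.5415978266378,2.66050215550884,0.133435764019051
1575,375,1.07201840779638,1.20936739554423,-0.0274224192485538,-0.0438266948490494,34.7179985320842,2.9408055324768,0.10016864921704
1550,400,0.974989057571479,1.13686462246301,-0.0948722650039058,-0.0618232671704595,38.0742330292108,3.18158619419898,0.078696341177968
1525,425,1.0033040582507,1.1343617152242,0.0286276428946466,-0.00220401481831242,37.9515457617321,3.35424607087639,0.0528471514627822
1500,450,1.01699168336559,1.17584346272425,0.0135503275742667,0.0359156033827792,37.9223799779482,3.63521374826235,0.080440884978743
1475,475,1.00224366612109,1.16608827589457,-0.0146077865571976,-0.00833093731120599,40.2031108880033,3.91194197207688,0.0733660066690054
1450,500,1.06405674171013,1.21853426027696,0.0598475653116256,0.0439939170749257,41.733419578638,4.21848278091893,0.0754416140644973
1425,525,1.09910016117004,1.2445479911363,0.0324030915584446,0.0211236942145217,42.4120988338325,4.7289185868204,0.114221014971775
1400,550,1.08717736552344,1.28136653482136,-0.010907045147792,0.0291547091090272,43.7352247589257,5.25079677171346,0.104683283343744
1375,575,1.10246588775278,1.26586213221558,0.0139646224632658,-0.0121736962871641,44.4653069288951,5.85299942011721,0.108574420105731
1350,600,1.1340307425234,1.31750453407515,0.0282289277007093,0.0399860253624591,43.3512015031925,6.6624625028109,0.129534910145577
1325,625,1.1079310133076,1.30102618852813,-0.0232839907181372,-0.0125861139855731,37.5065171324819,7.42704568835873,0.108638998945333
1300,650,1.04031154513804,1.16802626751563,-0.0629740931028629,-0.10783795540067,27.0927955009329,7.99398280836737,0.0735609493942824
1275,675,0.861541534350799,0.967156714605698,-0.188552243435759,-0.188710107450123,26.7395274258767,8.307996897732,0.0385294228866631
1250,700,0.835768757523737,0.959093810019538,-0.0303712974830644,-0.00837165423030623,26.2177127246086,8.24856383201958,-0.007179428381062
1225,725,0.815295948157164,0.931752771626099,-0.0248007950898303,-0.0289213777655797,22.6443644583286,8.23527591440501,-0.00161223606844851
1200,750,0.762707381618156,0.890685289431303,-0.0666767265040798,-0.0450763584381384,22.1679314344022,8.00885817925676,-0.027878666643979
1175,775,0.750010828206663,0.863382686754803,-0.0167868033604731,-0.0311331240456635,23.937404892001,7.76420643020316,-0.0310239484345973
1150,800,0.748115457724899,0.882499512157984,-0.00253032272489623,0.0219002054950052,27.6107548372705,7.42953102545889,-0.0440615153907626
1125,825,0.821804656524816,0.934301060109274,0.0939454013738225,0.0570404844426387,27.0419133241932,7.38125374010755,-0.00651923002040533
1100,850,0.820449666228824,0.95226524619567,-0.00165015927763595,0.0190448954830176,27.7639425270971,7.24966110555312,-0.0179887839548167
1075,875,0.849238130828665,0.95292278696323,0.0344870674739156,0.000690263409410363,27.2820219242787,7.38955757790651,0.0191131417839128
1050,900,0.83240976071732,0.945359156228981,-0.0200148104355978,-0.00796896455588805,23.7206746030343,7.27822817064597,-0.0151804160632374
1025,925,0.779124597096668,0.897017866305227,-0.0661538424385857,-0.052489135087491,23.1805527305082,7.15203555469838,-0.0174904402797091
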