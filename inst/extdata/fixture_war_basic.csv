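"year","N","W","C"
50,0.0498032431742493,0.503062975446168,31.8677309462883
75,0.0714882474098991,0.454986215144253,33.0451147296969
100,0.103351528043171,0.419276649360103,30.9292059465274
125,0.145152289910094,0.397282660675272,36.5292071636353
150,0.203782608523361,0.372603652047127,37.2118890463543
175,0.284213002019315,0.360032634372067,34.3081060847294
200,0.387792360470083,0.355102769330261,35.908772025069
225,0.510451644725711,0.358274091406206,37.9419917354428
250,0.644300109385154,0.377583692752114,39.0809374433147
275,0.791164534234641,0.416861099716091,37.3485847931827
300,0.933045349103492,0.485374267063378,41.4142113398987
325,1.06024465263012,0.564984721000907,41.3008987811533
350,1.1412688728161,0.715951254671045,38.1769972832972
375,1.19939069552409,0.91029402899833,30.8974981651053
400,1.18790151961383,1.18527477993513,35.0927912865135
425,1.17308553773206,1.50871204469762,34.9394322021651
450,1.16393002286283,1.95831519174817,34.9029749724353
475,1.11184155465827,2.50689572584297,37.7538886100041
500,1.09971713980228,3.15279661646379,39.6667744732976
525,1.05301591676144,4.0189265740214,40.5151235422906
550,0.96207485501857,4.95427248514112,42.1690309486571
575,0.878991955869984,5.96156321775819,43.0816336611189
600,0.805364830267676,7.10404470575608,41.6890018789907
625,0.702347678466805,8.0899107162308,34.3831464156024
650,0.607855475795061,8.87515650884448,36.3659943761661
675,0.498739564852341,9.66313898590347,35.9244092823459
700,0.419945636736776,10.0894029767394,35.2721409057607
725,0.348831589137811,10.4240486238127,30.8054555729107
750,0.288116409677095,10.4569415467957,30.2099142930027
775,0.245364430619096,10.3913175890955,32.4217561150013
800,0.208343768695495,10.0232833997751,37.0134435465882
825,0.193275797391966,9.76927014872614,36.3023916552415
850,0.174834564293776,9.28365004023231,37.2049281588713
875,0.16779964133626,9.06883273602624,36.6025274053484
900,0.158443909092682,8.53005458059378,32.1508432537929
925,0.151650683083735,8.10789365282035,31.4756909131353
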