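r,g,b,L_ref,a_ref,b_ref
0,0,0,0.000000,0.000000,0.000000
0,0,85,5.921942,34.685198,-48.120896
0,0,170,19.643108,58.440445,-79.600701
0,0,255,32.295673,79.185591,-107.857300
0,63,0,22.141431,-31.687867,29.700566
0,63,85,24.355196,-8.933593,-18.261765
0,63,170,30.534576,27.569663,-61.547860
0,63,255,39.193289,58.596698,-96.361260
0,127,0,45.876894,-51.407269,49.615816
0,127,85,46.755271,-40.692215,14.596486
0,127,170,49.591699,-13.476199,-31.012712
0,127,255,54.443407,19.397792,-71.352734
0,191,0,67.471280,-69.347866,66.931215
0,191,85,67.958006,-63.166643,41.825634
0,191,170,69.583731,-44.810707,-0.759723
0,191,255,72.545792,-17.662129,-42.536470
0,255,0,87.735099,-86.183030,83.179703
0,255,85,88.051120,-82.112547,64.673876
0,255,170,89.119215,-69.231648,26.820216
0,255,255,91.113301,-48.090596,-14.126330
63,0,0,9.458452,29.448424,14.933079
63,0,85,13.901016,40.406918,-34.681543
63,0,170,23.532596,60.024980,-73.012886
63,0,255,34.547159,79.977047,-104.039838
63,63,0,25.599253,-7.925248,34.287731
63,63,85,27.483736,5.572181,-13.171721
63,63,170,32.947262,33.273130,-57.505049
63,63,255,40.942768,60.945630,-93.409060
63,127,0,47.281316,-39.595994,51.323509
63,127,85,48.121901,-30.688978,16.684872
63,127,170,50.845991,-7.015730,-28.963397
63,127,255,55.534804,23.086347,-69.534308
63,191,0,68.253336,-62.433186,67.884488
63,191,85,68.731145,-56.749058,42.936950
63,191,170,70.328155,-39.678919,0.416850
63,191,255,73.241825,-14.001699,-41.398164
63,255,0,88.243722,-81.604861,83.800194
63,255,85,88.556680,-77.715194,65.366983
63,255,170,89.614625,-65.362247,27.575731
63,255,255,91.590561,-44.959375,-13.363003
127,0,0,25.301281,47.774218,37.753817
127,0,85,27.211276,52.835969,-12.755501
127,0,170,32.732636,66.057949,-57.535838
127,0,255,40.784438,83.092789,-93.496209
127,63,0,34.124823,24.092976,44.499600
127,63,85,35.447262,30.255737,-0.421104
127,63,170,39.528852,46.627690,-46.538665
127,63,255,46.022435,67.609595,-84.860446
127,127,0,51.486524,-12.857140,56.355204
127,127,85,52.227315,-7.050011,22.897814
127,127,170,54.650055,9.715955,-22.773743
127,127,255,58.889378,33.470941,-63.957218
127,191,0,70.714167,-43.536060,70.862813
127,191,85,71.165452,-39.019953,46.415776
127,191,170,72.676773,-25.092293,4.117681
127,191,255,75.445077,-3.237286,-37.801086
127,255,0,89.873051,-68.066685,85.780318
127,255,85,90.176492,-64.666192,67.579808
127,255,170,91.202866,-53.761782,29.992427
127,255,255,93.122222,-35.435304,-10.916614
191,0,0,39.714994,64.446918,54.075233
191,0,85,40.792872,67.356101,8.781598
191,0,170,44.205812,76.095016,-38.480383
191,0,255,49.854331,89.369073,-78.256725
191,63,0,45.129997,49.283084,56.411716
191,63,85,46.029505,52.584424,16.020233
191,63,170,48.928313,62.519596,-31.051304
191,63,255,53.869386,77.574688,-71.727848
191,127,0,58.281098,16.729736,64.256415
191,127,85,58.894228,20.301651,32.790683
191,127,170,60.921692,31.307035,-12.656604
191,127,255,64.543577,48.552948,-54.599997
191,191,0,75.038612,-17.344147,76.022579
191,191,85,75.448329,-14.070580,52.462219
191,191,170,76.824533,-3.680479,10.611350
191,191,255,79.360732,13.451931,-31.431876
191,255,0,92.837304,-46.872270,89.354038
191,255,85,93.124506,-44.118301,71.576557
191,255,170,94.096906,-35.173867,34.374732
191,255,255,95.919132,-19.779597,-6.462649
255,0,0,53.240588,80.092308,67.202751
255,0,85,53.944887,82.005692,28.689672
255,0,170,56.255741,88.097063,-18.816304
255,0,255,60.323507,98.233054,-60.821015
255,63,0,56.901492,69.673851,68.652143
255,63,85,57.537747,71.745820,33.197514
255,63,170,59.637609,78.342588,-13.687726
255,63,255,63.374951,89.307515,-55.951034
255,127,0,66.858542,43.316851,73.901189
255,127,85,67.352429,45.619011,44.989404
255,127,170,69.001180,52.998664,0.206775
255,127,255,72.001927,65.396386,-42.344854
255,191,0,81.030694,10.384338,83.030023
255,191,85,81.391651,12.704288,60.698820
255,191,170,82.608109,20.236013,19.574104
255,191,255,84.865421,33.187938,-22.530594
255,255,0,97.139507,-21.554681,94.478122
255,255,85,97.405359,-19.416739,77.311506
255,255,170,98.306598,-12.388252,40.699785
255,255,255,100.000000,-0.002455,0.004653
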