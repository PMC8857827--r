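# name: synthetic demonstration newborn-size standard
# citation: synthetic stand-in shipped with customgrowth; NOT a published standard
# construction: location = term median (3250 g male / 3100 g female) x proportionality fraction; scale = 0.135 x location
sex,ga_weeks,location_g,scale_g
male,24,617.5,83.4
male,25,707.1,95.5
male,26,816.3,110.2
male,27,943.2,127.3
male,28,1085.6,146.6
male,29,1241.5,167.6
male,30,1408.9,190.2
male,31,1585.6,214.1
male,32,1769.7,238.9
male,33,1959.1,264.5
male,34,2151.7,290.5
male,35,2345.5,316.6
male,36,2538.4,342.7
male,37,2728.3,368.3
male,38,2913.2,393.3
male,39,3091,417.3
male,40,3259.8,440.1
male,41,3417.3,461.3
male,42,3561.6,480.8
female,24,589,79.5
female,25,674.4,91
female,26,778.6,105.1
female,27,899.6,121.4
female,28,1035.5,139.8
female,29,1184.2,159.9
female,30,1343.9,181.4
female,31,1512.5,204.2
female,32,1688.1,227.9
female,33,1868.7,252.3
female,34,2052.4,277.1
female,35,2237.2,302
female,36,2421.2,326.9
female,37,2602.4,351.3
female,38,2778.7,375.1
female,39,2948.4,398
female,40,3109.3,419.8
female,41,3259.6,440
female,42,3397.2,458.6
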