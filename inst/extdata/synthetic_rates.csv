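# half-open age bands [age_start, age_end); rates per 100000 person-years
age_start,age_end,incidence_per_100k,mortality_per_100k
18,20,7.74113056002759,52.8270307337747
20,25,12.2013639433065,64.0409681191861
25,30,21.2658670123907,84.3118989771279
30,35,33.1667458895054,110.999201259729
35,40,46.2879226630668,146.133853344238
40,45,57.8066198662083,192.389700564296
45,50,64.6,253.286942321492
50,55,64.6,333.46002910967
55,60,57.8066198662083,439.01035716513
60,65,46.2879226630668,577.970601792485
65,70,33.1667458895054,760.916026431505
70,75,21.2658670123907,1001.76928979546
75,80,12.2013639433065,1318.85999915607
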