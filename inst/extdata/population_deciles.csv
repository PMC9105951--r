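decile,births_thousands,mean_hb_gdl,hb_sd_gdl,income_share_pct
1,436,10.4,1.4,1.92
2,427,10.4,1.4,3.21
3,418,10.5,1.4,4.23
4,413,10.6,1.4,5.18
5,400,10.8,1.4,6.28
6,376,10.9,1.4,7.6
7,371,11.1,1.4,9.29
8,370,11.1,1.4,11.6
9,357,11.2,1.4,15.9
10,355,11.2,1.4,34.8
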