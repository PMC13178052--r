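stream,label,year,n,mean_age,sd_age,n_male
ambulatory,diagnosed,2018,72309,57.25,21.35,32674
ambulatory,diagnosed,2019,77445,57.83,21.33,35637
ambulatory,diagnosed,2020,63905,59.86,19.75,30663
ambulatory,diagnosed,2021,90842,60.26,19.16,44431
ambulatory,diagnosed,2022,123155,61.15,18.18,62291
ambulatory,potential,2018,49242,61.02,14.55,26462
ambulatory,potential,2019,52659,61.94,14.06,28810
ambulatory,potential,2020,42603,62.45,13.41,23556
ambulatory,potential,2021,50986,62.48,13.96,28139
ambulatory,potential,2022,51351,62.66,14.49,28136
mortality,diagnosed,2018,108430,74.68,17.42,53239
mortality,diagnosed,2019,109758,74.88,17.14,53935
mortality,diagnosed,2020,117849,74.79,15.98,58719
mortality,diagnosed,2021,131981,74.88,16.02,65535
mortality,diagnosed,2022,131411,75.36,16.41,64342
mortality,potential,2018,187856,70.75,21.57,105724
mortality,potential,2019,191612,70.97,21.16,107688
mortality,potential,2020,194111,71.30,19.20,110659
mortality,potential,2021,213606,71.12,19.07,120797
mortality,potential,2022,201418,71.47,19.52,113179
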