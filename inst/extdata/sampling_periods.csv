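season,start,end,fix_rate_mean,fix_rate_sd,valid_positions,ehpe_mean_cm,ehpe_sd_cm,n_animals,herd_size
winter,2019-02-26,2019-03-03,96.2,3.3,27594,897,768,3,12
winter,2020-12-14,2021-01-17,51.1,49.1,17173,1374,734,2,12
spring,2019-04-06,2019-04-18,97.9,2.6,36594,648,504,3,12
spring,2020-06-03,2020-07-08,63.1,39.7,20385,1515,821,3,12
summer,2019-07-16,2019-07-24,89.8,2.0,11639,1553,879,3,12
summer,2020-08-05,2020-09-16,69.5,5.4,8364,1654,979,3,12
autumn,2019-09-26,2019-10-16,93.1,2.2,28149,1446,777,3,12
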