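survey,row,quantity,weighted_count,external_count,percent_printed,ci_low_printed,ci_high_printed,unweighted_n
nsfg,five_year_recall_ftf,abortion,4575254,11413954,40,36,44,1180
nsfg,ftf_2006_2010,abortion,2367494,6043097,39,33,45,612
nsfg,ftf_2011_2015,abortion,2207760,5370857,41,35,47,568
nsfg,three_year_recall_ftf,abortion,2663486,6731802,40,35,44,705
nsfg,eight_year_recall_ftf,abortion,7143890,18499516,39,35,43,1787
nsfg,five_year_recall_acasi,abortion,8272507,11413954,72,65,80,1976
nlsy,all_women,population,9438553,10663010,89,83,94,3595
nlsy,all_women,birth,4977553,5787668,86,79,93,1938
nlsy,all_women,abortion,437223,1470682,30,24,35,188
nlsy,excl_foreign_born,population,8983726,8568894,105,98,111,3355
nlsy,excl_foreign_born,birth,4764155,4403888,108,99,118,1804
nlsy,excl_foreign_born,abortion,409757,1235495,33,27,39,173
addhealth,all_women,population,10029020,12183021,82,75,90,7357
addhealth,all_women,birth,4848152,6794737,71,63,80,3555
addhealth,all_women,abortion,615780,1969832,31,25,37,529
addhealth,excl_non_hs_grads,population,8476026,10294653,82,74,90,6392
addhealth,excl_non_hs_grads,birth,3972409,5524597,72,63,81,3004
addhealth,excl_non_hs_grads,abortion,481352,1733861,28,22,34,443
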