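qtl,closest_marker,chr,pos_cM,lod,lower_bp,upper_bp
SSH.qtl1,mCV24784983,1,10.5,12,5920984,25974921
SSH.qtl2,rs3678634,1,52.6,28.3,115819089,127021793
SSH.qtl3,rs13466711,1,78.6,17.7,168066210,175710316
SSH.qtl4,rs13480734,10,52.9,18.3,89335908,105325377
SSH.qtl5,rs13481127,11,48.5,27.3,80139712,81911051
SSH.qtl6,rs3672597,11,77.5,24.8,112611769,114027932
SSH.qtl7,rs3717860,12,8.8,32.5,16866101,28237591
SSH.qtl8,rs3710348,13,13.4,19.5,30941216,35713142
SSH.qtl9,gnf13.115.241,13,62.8,13.4,110281304,118066332
SSH.qtl10,rs6396829,14,20.1,28.1,30970692,38186621
SSH.qtl11,CEL-15_43206205,15,16.8,15,39391647,47392759
SSH.qtl12,rs4191367,16,35.4,13.9,54657678,66961706
SSH.qtl13,rs6298471,17,19.2,23.8,36252692,43916321
SSH.qtl14,rs6328845,18,31.3,11.4,56230871,70306352
SSH.qtl15,rs3023496,19,40.1,17,46867039,49396956
SSH.qtl16,rs13476580,2,44.3,20.6,72637926,76844869
SSH.qtl17,rs6209325,2,73.3,16.5,146817118,155755548
SSH.qtl18,rs6246699,3,18,14.6,34942416,39449337
SSH.qtl19,rs4138887,3,44,13.4,96754992,130100724
SSH.qtl20,rs3660863,4,3.1,9.7,3867296,11352972
SSH.qtl21,rs3711477,4,40.1,20.5,81877569,105794559
SSH.qtl22,rs3663950,4,65.1,23.2,126198546,134724460
SSH.qtl23,rs13459085,5,17.3,24.8,20284721,35523469
SSH.qtl24,CEL-5_117374791,5,59.3,14.7,117729579,119888175
SSH.qtl25,rs6181382,6,35.5,34.8,78232602,84781463
SSH.qtl26,rs6265387,6,78.2,27.3,144446852,148260112
SSH.qtl27,rs13479395,7,49.5,16.4,78470627,90617547
SSH.qtl28,rs13479776,8,29.7,23.2,47753313,78304228
SSH.qtl29,rs3714664,9,22.5,11.3,39523343,46544750
SSH.qtl30,rs13480351,9,49.5,16,90683187,99809852
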