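day,measure,value
0,n_total,8
NA,first_litter_day,104
315,n_total,620
315,n_adult,150
560,n_total,2200
NA,last_litter_day,600
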