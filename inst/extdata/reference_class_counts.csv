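sample,group,n_group,mean_bmi,n_normal,n_overweight,n_obese
population,near_nil,182,25.7,90,60,31
population,low,660,25.9,333,199,123
population,medium,434,26.1,213,123,93
population,high,112,26.8,48,34,28
population,missing_p,223,25.4,129,61,31
population,not_working,1766,26.7,738,619,383
alumni,near_nil,260,24.6,159,69,25
alumni,low,464,24.0,313,103,40
alumni,medium,274,24.3,177,67,23
alumni,high,69,23.9,46,19,2
alumni,missing_p,30,23.9,17,10,0
alumni,not_working,1056,24.3,656,271,93
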