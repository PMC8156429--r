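variety,vintage,n
TF,2012,240
TF,2013,81
TF,2014,120
TF,2016,407
TF,2017,540
TF,2018,360
TN,2013,60
TN,2014,118
TN,2016,132
TN,2017,144
TB,2013,82
TB,2014,120
TB,2016,143
TB,2017,118
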