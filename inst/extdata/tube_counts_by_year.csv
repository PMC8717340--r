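region,year,n_positive,n_negative
Taoyuan,2008,1861,29764
Taoyuan,2009,1941,46234
Taoyuan,2010,2785,52045
Taoyuan,2011,1416,18081
Hsinchu,2012,224,16979
Hsinchu,2013,178,15644
Hsinchu,2014,377,19247
Hsinchu,2015,742,11095
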