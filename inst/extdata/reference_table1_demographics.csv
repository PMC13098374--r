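variable,value,range_low,range_high,note
n_dogs,20,NA,NA,
age_years,10.38,6,14,mean (range)
male,13,NA,NA,count
female,7,NA,NA,count
body_weight_kg,9.84,4.3,19.6,mean (range)
LVIDdN,1.84,1.7,2.05,mean (range)
LA_Ao,1.83,1.61,2.5,mean (range)
pimobendan_mg_kg_day,0.57,0.5,0.64,mean (range)
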