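characteristic,category,total,l858r,del19,wt
patients,n,31,8,7,16
age,median,66,66,66,67
age,range,49-87,52-86,49-76,53-87
sex,male_female,21:10,5:3,3:4,13:3
stage,II,1,0,0,1
stage,III,6,0,0,6
stage,IV,24,8,7,9
double_pos_bucket,ge_30.1,10,5,5,0
double_pos_bucket,lt_30.1,21,3,2,16
tki_therapy,n,15,8,7,0
tki_response,CR_PR,9,3,6,
tki_response,SD,3,3,0,
tki_response,PD,1,0,1,
tki_response,NE,2,2,0,
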