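patient_id,smoker,years_smoking,GOLD_group,FEV1,FVC,FEV1_FVC,DLCO,mMRC
P01,NO,NA,C,113,114,67,97,1
P02,EX,50,A,64,100,41,105,0
P03,YES,50,A,75,62,63,122,1
P04,NO,NA,D,39,56,54,97,2
P05,EX,40,C,75,113,47,94,1
P06,EX,40,B,27,86,21,35,2
P07,EX,40,B,70,91,56,86,2
P08,EX,30,D,33,47,52,55,4
P09,NO,NA,D,77,85,67,73,1
P10,EX,20,C,69,99,47,89,2
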