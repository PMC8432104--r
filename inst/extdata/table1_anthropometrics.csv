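pair,group,gender,age_y,weight_kg,height_cm
1,COPD,F,73,64,145
2,COPD,M,50,87,183
3,COPD,M,74,60,170
4,COPD,F,39,52,156
5,COPD,F,80,67,165
6,COPD,M,68,51,171
7,COPD,F,64,79,167
8,COPD,M,56,80,168
9,COPD,F,60,58,157
10,COPD,M,66,90,166
1,control,M,65,63,159
2,control,M,60,85,179
3,control,M,67,90,174
4,control,F,63,65,163
5,control,M,78,68,169
6,control,F,68,70,163
7,control,M,61,65,165
8,control,F,63,62,163
9,control,F,58,84,153
10,control,F,58,49,152
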