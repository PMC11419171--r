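cluster	label	n
1	pain_comorbidities	441
2	uterine_disorders	686
3	pregnancy_complications	1151
4	cardiometabolic_comorbidities	796
5	ehr_asymptomatic	1004
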