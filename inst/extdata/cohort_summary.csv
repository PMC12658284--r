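patient,age,sex,icu_stay_days,icu_death,seizure_type,clustered,analyzed_seizures,mean_seizure_duration_s,sd_seizure_duration_s,recording_hours
01,20,M,65,no,focal_to_bilateral,yes,258,97,30,152
02,35,M,93,no,focal_to_bilateral,yes,62,126,36,45
03,32,F,64,no,focal_to_bilateral,yes,106,70,16,24
04,39,M,46,yes,focal_to_bilateral,yes,72,119,16,21
05,22,M,67,no,focal_to_bilateral,yes,68,89,49,71
06,20,M,126,no,focal_to_bilateral,no,62,163,13,10
07,26,M,38,no,focal_to_bilateral,no,84,145,18,57
08,51,M,36,yes,focal,no,306,46,15,29
09,18,M,17,no,focal,no,120,144,59,39
10,59,M,48,yes,focal,no,92,182,52,20
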