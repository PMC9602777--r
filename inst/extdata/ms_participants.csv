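id,group,sex,age_yr,height_m,mass_kg,ethnicity,edss,ms_type,medications
1,MS,M,38,1.66,69.0,A,1,RR,
2,MS,F,58,1.73,68.9,WE,6.5,RR,
3,MS,F,59,1.60,47.8,WE,6.5,PP,
4,MS,M,44,1.78,76.3,WE,1,RR,
5,MS,F,51,1.57,99.4,WE,6.5,PP,Baclofen
6,MS,M,63,1.97,96.0,WE,6.5,SP,
7,MS,F,33,1.68,104.7,WE,3.5,RR,
8,MS,M,61,1.78,89.5,WE,6,PP,
9,MS,F,53,1.74,61.1,WE,6,PP,
10,MS,M,47,1.92,77.6,WE,7,RR,Copaxone
11,MS,F,33,1.63,63.7,WE,3.5,RR,
12,MS,F,40,1.61,63.6,A,3,RR,
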