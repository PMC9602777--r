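participant_id,site,quality,wetness_mm,z
1,FOREHEAD,COLD_WET,0,-5.31
1,FOREHEAD,NEUTRAL_WET,39,0.39
1,FOREHEAD,WARM_WET,0,-3.28
2,FOREHEAD,COLD_WET,3,-2.26
2,FOREHEAD,NEUTRAL_WET,59,0.59
2,FOREHEAD,WARM_WET,46,0.42
3,FOREHEAD,COLD_WET,14,-0.92
3,FOREHEAD,NEUTRAL_WET,28,0.22
3,FOREHEAD,WARM_WET,26,0.08
4,FOREHEAD,COLD_WET,62,0.39
4,FOREHEAD,NEUTRAL_WET,34,0.32
4,FOREHEAD,WARM_WET,1,-1.83
5,FOREHEAD,COLD_WET,88,0.70
5,FOREHEAD,NEUTRAL_WET,57,0.58
5,FOREHEAD,WARM_WET,30,0.16
6,FOREHEAD,COLD_WET,48,0.17
6,FOREHEAD,NEUTRAL_WET,56,0.57
6,FOREHEAD,WARM_WET,52,0.50
7,FOREHEAD,COLD_WET,95,0.77
7,FOREHEAD,NEUTRAL_WET,90,0.81
7,FOREHEAD,WARM_WET,86,0.80
8,FOREHEAD,COLD_WET,63,0.41
8,FOREHEAD,NEUTRAL_WET,56,0.57
8,FOREHEAD,WARM_WET,58,0.56
9,FOREHEAD,COLD_WET,98,0.80
9,FOREHEAD,NEUTRAL_WET,79,0.74
9,FOREHEAD,WARM_WET,19,-0.11
10,FOREHEAD,COLD_WET,73,0.54
10,FOREHEAD,NEUTRAL_WET,58,0.59
10,FOREHEAD,WARM_WET,62,0.60
11,FOREHEAD,COLD_WET,60,0.37
11,FOREHEAD,NEUTRAL_WET,34,0.32
11,FOREHEAD,WARM_WET,24,0.03
12,FOREHEAD,COLD_WET,97,0.79
12,FOREHEAD,NEUTRAL_WET,79,0.74
12,FOREHEAD,WARM_WET,76,0.72
1,FINGER_PAD,COLD_WET,46,-0.80
1,FINGER_PAD,NEUTRAL_WET,44,0.01
1,FINGER_PAD,WARM_WET,0,-3.34
2,FINGER_PAD,COLD_WET,62,-0.04
2,FINGER_PAD,NEUTRAL_WET,0,-8.52
2,FINGER_PAD,WARM_WET,1,-1.92
3,FINGER_PAD,COLD_WET,55,-0.35
3,FINGER_PAD,NEUTRAL_WET,63,0.52
3,FINGER_PAD,WARM_WET,76,0.60
4,FINGER_PAD,COLD_WET,65,0.08
4,FINGER_PAD,NEUTRAL_WET,70,0.66
4,FINGER_PAD,WARM_WET,52,0.38
5,FINGER_PAD,COLD_WET,82,0.67
5,FINGER_PAD,NEUTRAL_WET,46,0.08
5,FINGER_PAD,WARM_WET,24,-0.08
6,FINGER_PAD,COLD_WET,32,-1.73
6,FINGER_PAD,NEUTRAL_WET,69,0.64
6,FINGER_PAD,WARM_WET,63,0.49
7,FINGER_PAD,COLD_WET,62,-0.04
7,FINGER_PAD,NEUTRAL_WET,33,-0.39
7,FINGER_PAD,WARM_WET,91,0.71
8,FINGER_PAD,COLD_WET,56,-0.30
8,FINGER_PAD,NEUTRAL_WET,60,0.45
8,FINGER_PAD,WARM_WET,66,0.52
9,FINGER_PAD,COLD_WET,48,-0.69
9,FINGER_PAD,NEUTRAL_WET,48,0.14
9,FINGER_PAD,WARM_WET,61,0.47
10,FINGER_PAD,COLD_WET,0,-16.47
10,FINGER_PAD,NEUTRAL_WET,23,-0.89
10,FINGER_PAD,WARM_WET,0,-3.34
11,FINGER_PAD,COLD_WET,51,-0.54
11,FINGER_PAD,NEUTRAL_WET,52,0.25
11,FINGER_PAD,WARM_WET,55,0.41
12,FINGER_PAD,COLD_WET,63,0.00
12,FINGER_PAD,NEUTRAL_WET,55,0.33
12,FINGER_PAD,WARM_WET,49,0.34
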