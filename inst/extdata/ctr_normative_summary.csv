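site,quality,n,mean_mm,sd_mm
FOREHEAD,COLD_WET,51,53.7,27.4
FOREHEAD,NEUTRAL_WET,51,40.6,29.3
FOREHEAD,WARM_WET,51,41.3,28.6
FINGER_PAD,COLD_WET,31,67.7,21.1
FINGER_PAD,NEUTRAL_WET,31,51.7,24.2
FINGER_PAD,WARM_WET,31,47.6,28.6
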