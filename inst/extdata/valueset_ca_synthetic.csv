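dimension,level,decrement
physical,1,0
physical,2,0.05
physical,3,0.12
physical,4,0.20
role,1,0
role,2,0.03
role,3,0.07
role,4,0.12
social,1,0
social,2,0.025
social,3,0.06
social,4,0.10
emotional,1,0
emotional,2,0.03
emotional,3,0.065
emotional,4,0.11
pain,1,0
pain,2,0.045
pain,3,0.11
pain,4,0.18
fatigue,1,0
fatigue,2,0.025
fatigue,3,0.055
fatigue,4,0.09
sleep,1,0
sleep,2,0.015
sleep,3,0.035
sleep,4,0.06
appetite,1,0
appetite,2,0.015
appetite,3,0.035
appetite,4,0.06
nausea,1,0
nausea,2,0.02
nausea,3,0.04
nausea,4,0.07
bowel,1,0
bowel,2,0.015
bowel,3,0.035
bowel,4,0.06
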