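c30_item,dimension,level_rule
2,physical,direct
3,physical,direct
6,role,direct
26,social,direct
24,emotional,direct
9,pain,direct
19,pain,direct
18,fatigue,direct
11,sleep,direct
13,appetite,direct
14,nausea,direct
16,bowel,direct
17,bowel,direct
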