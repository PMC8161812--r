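name,baseline,lower,upper
p_sse_4wk,0.203,0.1338,0.2954
p_no_sse_4wk,0.797,0.6525,0.9639
p_sse_12wk,0.223,NA,NA
p_no_sse_12wk,0.777,NA,NA
relative_risk,1.099,0.6902,1.7496
cost_bta_4wk,5642.07,4513.66,6770.48
cost_bta_12wk,1826.73,1461.38,2192.08
cost_sse_4wk,16369.25,13095.40,19643.10
cost_sse_12wk,17234.19,13787.35,20681.03
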