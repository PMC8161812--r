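item,category,arm,unit_cost,weight
denosumab_120mg,DRUG,FOUR_WEEKLY,594.05,0.6131188184
zoledronate_4mg,DRUG,FOUR_WEEKLY,124.08,0.2468811816
pamidronate_90mg,DRUG,FOUR_WEEKLY,225.48,0.14
denosumab_120mg,ADMINISTRATION,FOUR_WEEKLY,37.18,0.6131188184
zoledronate_4mg,ADMINISTRATION,FOUR_WEEKLY,50.15,0.2468811816
pamidronate_90mg,ADMINISTRATION,FOUR_WEEKLY,61.23,0.14
denosumab_120mg,DRUG,TWELVE_WEEKLY,594.05,0.5786776805
zoledronate_4mg,DRUG,TWELVE_WEEKLY,124.08,0.2613223195
pamidronate_90mg,DRUG,TWELVE_WEEKLY,225.48,0.16
denosumab_120mg,ADMINISTRATION,TWELVE_WEEKLY,37.18,0.5786776805
zoledronate_4mg,ADMINISTRATION,TWELVE_WEEKLY,50.15,0.2613223195
pamidronate_90mg,ADMINISTRATION,TWELVE_WEEKLY,61.23,0.16
radiotherapy,SSE_EVENT,FOUR_WEEKLY,7000.00,0.515375
fracture,SSE_EVENT,FOUR_WEEKLY,25000.00,0.15
cord_compression,SSE_EVENT,FOUR_WEEKLY,45000.00,0.08
surgery,SSE_EVENT,FOUR_WEEKLY,35000.00,0.12
hypercalcemia,SSE_EVENT,FOUR_WEEKLY,9000.00,0.134625
radiotherapy,SSE_EVENT,TWELVE_WEEKLY,7000.00,0.472905
fracture,SSE_EVENT,TWELVE_WEEKLY,25000.00,0.16
cord_compression,SSE_EVENT,TWELVE_WEEKLY,45000.00,0.09
surgery,SSE_EVENT,TWELVE_WEEKLY,35000.00,0.13
hypercalcemia,SSE_EVENT,TWELVE_WEEKLY,9000.00,0.147095
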