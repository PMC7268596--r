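review,review_type,workload_n,ta_includes,ft_includes,screened_training,training_includes,predicted_relevant
Biomarkers,systematic,1812,209,45,200,14,503
Brain injury,systematic,6262,518,40,200,11,2126
Activity and pregnancy,systematic,2928,236,98,200,10,319
Concussion,systematic,1439,46,5,200,3,638
Antipsychotics,systematic,12156,1177,127,200,15,2117
Digital technologies for pain,systematic,2662,207,64,200,15,321
Treatments for bronchiolitis,systematic,5861,518,137,200,12,656
VBAC,systematic,5092,807,21,200,25,1490
Visual acuity,systematic,11229,224,1,300,4,3639
Experience of bronchiolitis,systematic,651,88,28,200,13,111
Experiences of UTIs,systematic,1493,25,4,200,3,864
Preterm delivery,rapid,451,96,34,200,47,95
Community gardening,rapid,1536,153,32,200,55,139
Depression safety,rapid,964,44,8,200,7,449
Depression treatments,rapid,1583,418,179,200,43,904
Patient education for cancer,rapid,2413,153,1,200,5,1410
Workplace stress,rapid,767,141,59,200,36,210
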