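review,strategy,savings_records,savings_pct,hours,days
Biomarkers,single_full_auto,3424,94,29,4
Biomarkers,single_semi_auto,2921,85,24,3
Brain injury,single_full_auto,12324,98,103,13
Brain injury,single_semi_auto,10198,81,85,11
Activity and pregnancy,single_full_auto,5656,97,47,6
Activity and pregnancy,single_semi_auto,5337,91,44,6
Concussion,single_full_auto,2678,93,22,3
Concussion,single_semi_auto,2040,71,17,2
Antipsychotics,single_full_auto,24112,99,201,25
Antipsychotics,single_semi_auto,21995,90,183,23
Digital technologies for pain,single_full_auto,5124,96,43,5
Digital technologies for pain,single_semi_auto,4803,90,40,5
Treatments for bronchiolitis,single_full_auto,11522,98,96,12
Treatments for bronchiolitis,single_semi_auto,10866,93,91,11
VBAC,single_full_auto,9984,98,83,10
VBAC,single_semi_auto,8494,83,71,9
Visual acuity,single_full_auto,22258,99,185,23
Visual acuity,single_semi_auto,18619,83,155,19
Experience of bronchiolitis,single_full_auto,1102,85,9,1
Experience of bronchiolitis,single_semi_auto,991,76,8,1
Experiences of UTIs,single_full_auto,2786,93,23,3
Experiences of UTIs,single_semi_auto,1940,65,16,2
Preterm delivery,single_full_auto,251,56,2,<1
Preterm delivery,single_semi_auto,161,36,1,<1
Community gardening,single_full_auto,1336,87,11,1
Community gardening,single_semi_auto,1197,78,10,1
Depression safety,single_full_auto,764,79,6,<1
Depression safety,single_semi_auto,315,41,3,<1
Depression treatments,single_full_auto,1383,87,12,1
Depression treatments,single_semi_auto,479,30,4,<1
Patient education for cancer,single_full_auto,2213,92,18,2
Patient education for cancer,single_semi_auto,803,33,7,<1
Workplace stress,single_full_auto,567,74,5,<1
Workplace stress,single_semi_auto,357,47,3,<1
Biomarkers,dual_full_auto,1612,47,13,2
Biomarkers,dual_semi_auto,1109,32,9,1
Brain injury,dual_full_auto,6062,48,51,6
Brain injury,dual_semi_auto,3936,31,33,4
Activity and pregnancy,dual_full_auto,2728,47,23,3
Activity and pregnancy,dual_semi_auto,2409,41,20,3
Concussion,dual_full_auto,1239,43,10,1
Concussion,dual_semi_auto,601,21,5,<1
Antipsychotics,dual_full_auto,11956,49,100,12
Antipsychotics,dual_semi_auto,9839,40,82,10
Digital technologies for pain,dual_full_auto,2462,46,21,3
Digital technologies for pain,dual_semi_auto,2141,40,18,2
Treatments for bronchiolitis,dual_full_auto,5661,48,47,6
Treatments for bronchiolitis,dual_semi_auto,5005,43,42,5
VBAC,dual_full_auto,4892,48,41,5
VBAC,dual_semi_auto,3402,33,28,4
Visual acuity,dual_full_auto,11029,49,92,11
Visual acuity,dual_semi_auto,7390,33,62,8
Experience of bronchiolitis,dual_full_auto,451,35,4,<1
Experience of bronchiolitis,dual_semi_auto,340,26,3,<1
Experiences of UTIs,dual_full_auto,1293,43,11,1
Experiences of UTIs,dual_semi_auto,447,15,4,<1
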