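patient_id,sex,age,joint,isolate_1,isolate_2,mic_1,mic_2,prior_iv_days,infusion_h,second_stage,second_stage_culture_positive,interval_days,follow_up_days,clinical_cure
1,F,62,hip,S. epidermidis,,0.06,,7,2,1,0,45,400,1
2,F,65,hip,C. acnes,S. epidermidis,0.03,0.125,8,2,1,0,60,480,1
3,F,67,knee,S. epidermidis,,0.125,,9,0.5,1,0,70,550,1
4,M,68,hip,C. acnes,,0.06,,9,2,1,0,80,600,1
5,F,69,hip,S. epidermidis,,0.25,,10,0.5,1,0,85,630,1
6,F,69,knee,C. acnes,S. epidermidis,0.06,0.06,10,2,1,0,85,630,1
7,M,71,hip,S. epidermidis,,0.03,,10,0.5,1,0,95,650,1
8,F,73,knee,S. epidermidis,,0.125,,11,2,1,0,110,660,1
9,F,74,hip,C. acnes,S. capitis,0.03,0.25,11,0.5,1,0,120,680,1
10,M,75,knee,C. acnes,,0.06,,11,2,1,1,134,693,1
11,F,76,hip,S. epidermidis,,0.06,,12,0.5,1,0,140,700,1
12,F,77,knee,S. epidermidis,,0.125,,12,2,1,0,150,750,1
13,M,78,hip,C. acnes,S. epidermidis,0.06,0.125,13,0.5,1,0,160,790,1
14,F,78,knee,S. epidermidis,,0.06,,14,2,1,0,175,824,1
15,F,79,hip,S. epidermidis,,0.25,,16,0.5,1,0,175,824,1
16,M,79,shoulder,E. faecalis,,0.125,,16,2,1,0,180,850,1
17,F,81,hip,S. lugdunensis,,0.06,,17,0.5,1,0,200,900,1
18,M,83,shoulder,S. capitis,,0.125,,18,2,1,0,220,950,1
19,F,85,hip,S. hominis,,0.06,,20,0.5,1,0,260,1010,1
20,F,88,ankle,S. pettenkoferi,,0.06,,22,2,0,,,,1
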