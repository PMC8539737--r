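code_prefix,category_id,category_name,level
64,PREG,Pregnancy & childbirth complications,2
65,PREG,Pregnancy & childbirth complications,2
295,MENTAL,Mental illness,2
296,MENTAL,Mental illness,2
300,MENTAL,Mental illness,2
311,MENTAL,Mental illness,2
303,SUBST,Substance use disorders,2
304,SUBST,Substance use disorders,2
305,SUBST,Substance use disorders,2
340,NEURO,Neurologic disorders,2
345,NEURO,Neurologic disorders,2
348,NEURO,Neurologic disorders,2
250,ENDO,Endocrine & metabolic disorders,2
272,ENDO,Endocrine & metabolic disorders,2
401,CARDIO,Cardiovascular disease,2
410,CARDIO,Cardiovascular disease,2
414,CARDIO,Cardiovascular disease,2
428,CARDIO,Cardiovascular disease,2
486,RESP,Respiratory disease,2
491,RESP,Respiratory disease,2
493,RESP,Respiratory disease,2
714,MUSCULO,Musculoskeletal disorders,2
715,MUSCULO,Musculoskeletal disorders,2
724,MUSCULO,Musculoskeletal disorders,2
530,GI,Gastrointestinal disorders,2
558,GI,Gastrointestinal disorders,2
571,GI,Gastrointestinal disorders,2
585,GU,Genitourinary & renal disorders,2
590,GU,Genitourinary & renal disorders,2
599,GU,Genitourinary & renal disorders,2
820,INJURY,Injury & poisoning,2
850,INJURY,Injury & poisoning,2
965,INJURY,Injury & poisoning,2
V70,SCREEN,Screening & residual codes,2
780,SCREEN,Screening & residual codes,2
64,PREG_L1,Complications of pregnancy (L1),1
65,PREG_L1,Complications of pregnancy (L1),1
29,MENTAL_L1,Mental disorders (L1),1
30,MENTAL_L1,Mental disorders (L1),1
31,MENTAL_L1,Mental disorders (L1),1
34,NERV_L1,Nervous system (L1),1
25,ENDO_L1,Endocrine & metabolic (L1),1
27,ENDO_L1,Endocrine & metabolic (L1),1
40,CIRC_L1,Circulatory system (L1),1
41,CIRC_L1,Circulatory system (L1),1
42,CIRC_L1,Circulatory system (L1),1
48,RESP_L1,Respiratory system (L1),1
49,RESP_L1,Respiratory system (L1),1
71,MUSC_L1,Musculoskeletal system (L1),1
72,MUSC_L1,Musculoskeletal system (L1),1
53,DIG_L1,Digestive system (L1),1
55,DIG_L1,Digestive system (L1),1
57,DIG_L1,Digestive system (L1),1
58,GU_L1,Genitourinary system (L1),1
59,GU_L1,Genitourinary system (L1),1
82,INJ_L1,Injury & poisoning (L1),1
85,INJ_L1,Injury & poisoning (L1),1
96,INJ_L1,Injury & poisoning (L1),1
V7,RESID_L1,Residual & screening (L1),1
78,RESID_L1,Residual & screening (L1),1
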