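"treatment","parameter","level_or_name","mean","sd","source"
"MVD","bni_prob","I","52.8","21.3","BNI I"
"MVD","bni_prob","II","26.2","24.5","BNI II"
"MVD","bni_prob","III","13.3","5.1","BNI III"
"MVD","bni_prob","IV_V","7.7","0.67","BNI IV-V"
"MVD","complication_rate","","17.6","0.5","complications"
"MVD","recurrence_rate_7y","","15.9","10.5","7-year recurrence"
"MVD","retreat_fraction","","8","6.9","recurrences re-treated"
"MVD","complication_incidence","facial_numbness","0.044","0.02","facial_numbness"
"MVD","complication_utility","facial_numbness","0.96","0.014","Whitmore 2011"
"MVD","complication_incidence","facial_palsy","0.011","0.017","facial_palsy"
"MVD","complication_utility","facial_palsy","0.983","0.018","Whitmore 2011"
"MVD","complication_incidence","perioperative_death","0.002","0.001","perioperative_death"
"MVD","complication_utility","perioperative_death","0","0","Hunink 2001"
"MVD","complication_incidence","deafness","0.018","0.03","deafness"
"MVD","complication_utility","deafness","0.929","0.11","Whitmore 2011"
"MVD","complication_incidence","csf_leak","0.013","0.021","csf_leak"
"MVD","complication_utility","csf_leak","0.985","0","estimate"
"MVD","complication_incidence","meningitis_wound_infection","0.012","0.016","meningitis_wound_infection"
"MVD","complication_utility","meningitis_wound_infection","0.93","0.03","Whitmore 2011"
"MVD","complication_incidence","other_complications","0.033","0.005","other_complications"
"MVD","complication_utility","other_complications","1","0","residual category (model choice)"
"MVD","bni_utility","I","1","0","Hunink 2001"
"MVD","bni_utility","II","0.871","0.213","Perez 2009"
"MVD","bni_utility","III","0.739","0.221","Perez 2009; Spatz 2007"
"MVD","bni_utility","IV_V","0.399","0.189","Perez 2009"
"MVD","medication_probability","none","0.176","0.092","no medication complications"
"MVD","medication_utility","none","0.94","0.01","Spatz 2007"
"MVD","medication_probability","mild_moderate","0.514","0.144","mild-moderate medication complications"
"MVD","medication_utility","mild_moderate","0.912","0.037","Spatz 2007"
"MVD","medication_probability","severe","0.311","0.126","severe medication complications"
"MVD","medication_utility","severe","0.774","0.148","Spatz 2007"
"MVD","response_delay_months","","0","",""
"MVD","retreat_delay_months","","1","",""
"MVD","complication_onset_months","","0","",""
"MVD","retreat_modality_mix","MVD","0.8","",""
"MVD","retreat_modality_mix","SRS","0.2","",""
"SRS","bni_prob","I","38.8","17.5","BNI I"
"SRS","bni_prob","II","20.9","10.8","BNI II"
"SRS","bni_prob","III","25.5","12.7","BNI III"
"SRS","bni_prob","IV_V","14.8","6.4","BNI IV-V"
"SRS","complication_rate","","19.3","0.7","complications"
"SRS","recurrence_rate_7y","","22.6","13.4","7-year recurrence"
"SRS","retreat_fraction","","45.5","35.5","recurrences re-treated"
"SRS","complication_incidence","facial_numbness","0.141","0.053","facial_numbness"
"SRS","complication_utility","facial_numbness","0.96","0.014","Whitmore 2011"
"SRS","complication_incidence","facial_palsy","0.017","0.013","facial_palsy"
"SRS","complication_utility","facial_palsy","0.983","0.018","Whitmore 2011"
"SRS","complication_incidence","corneal_keratitis","0.015","0.009","corneal_keratitis"
"SRS","complication_utility","corneal_keratitis","0.963","0","van de Graaf 2010"
"SRS","complication_compound","corneal_keratitis","","","facial_numbness;facial_palsy"
"SRS","complication_incidence","hypertension_other","0.02","0.019","hypertension_other"
"SRS","complication_utility","hypertension_other","1","0","residual category (model choice)"
"SRS","bni_utility","I","1","0","Hunink 2001"
"SRS","bni_utility","II","0.871","0.213","Perez 2009"
"SRS","bni_utility","III","0.739","0.221","Perez 2009; Spatz 2007"
"SRS","bni_utility","IV_V","0.399","0.189","Perez 2009"
"SRS","medication_probability","none","0.176","0.092","no medication complications"
"SRS","medication_utility","none","0.94","0.01","Spatz 2007"
"SRS","medication_probability","mild_moderate","0.514","0.144","mild-moderate medication complications"
"SRS","medication_utility","mild_moderate","0.912","0.037","Spatz 2007"
"SRS","medication_probability","severe","0.311","0.126","severe medication complications"
"SRS","medication_utility","severe","0.774","0.148","Spatz 2007"
"SRS","response_delay_months","","1","",""
"SRS","retreat_delay_months","","3","",""
"SRS","complication_onset_months","","6","",""
"SRS","retreat_modality_mix","MVD","1","",""
"SRS","retreat_modality_mix","SRS","0","",""
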