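id,type,params,wording_source
antipsychotics,medication_class_in,"{""classes"":[""antipsychotic""]}",printed
anticonvulsants,medication_class_in,"{""classes"":[""anticonvulsant""]}",printed
strong-opioids,medication_class_in,"{""classes"":[""strong opioid""]}",printed
clozapine,medication_name_in,"{""names"":[""clozapine"",""clozaril"",""zaponex""]}",printed
lithium,medication_name_in,"{""names"":[""lithium"",""lithium carbonate"",""lithium citrate"",""priadel"",""camcolit""]}",printed
insulin,medication_class_in,"{""classes"":[""insulin""]}",printed
valproate,medication_name_in,"{""names"":[""valproate"",""sodium valproate"",""valproic acid"",""semisodium valproate"",""epilim"",""depakote""]}",printed
ckd-stage-3b,lab_compare,"{""lab"":""eGFR"",""op"":""between"",""lo"":30,""hi"":59,""units"":""mL/min""}",merged-group: covers CKD stages 3a-3b after merge
ckd-stage-4,lab_compare,"{""lab"":""eGFR"",""op"":""lt"",""value"":30,""units"":""mL/min""}",merged-group: covers CKD stages 4-5 after merge
covert-administration,flag_present,"{""flag"":""covert_administration""}",printed
high-creatine-kinase,lab_compare,"{""lab"":""creatine_kinase"",""op"":""gt"",""value"":400,""units"":""U/L""}",inferred threshold (adult ULN)
toxic-clozapine-levels,flag_present,"{""flag"":""toxic_clozapine_level""}",printed
toxic-lithium-levels,flag_present,"{""flag"":""toxic_lithium_level""}",printed
qtc-out-of-range,flag_present,"{""flag"":""qtc_outside_range""}",printed; merged group also covers QTc-prolonging medication
depot-antipsychotics,medication_class_in,"{""classes"":[""depot antipsychotic""]}",printed
zuclopenthixol-acuphase,medication_name_in,"{""names"":[""zuclopenthixol acetate"",""zuclopenthixol acuphase"",""clopixol acuphase""]}",printed
missed-doses,missed_dose_of,"{""any"":true}",printed
missed-doses-high-risk,missed_dose_of,"{""names"":[""clozapine"",""lithium"",""insulin"",""warfarin"",""methadone"",""valproate"",""phenytoin""]}",inferred high-risk list
acute-renal-impairment,flag_present,"{""flag"":""acute_kidney_injury""}",printed
no-review-7-days,days_since_event_ge,"{""event"":""last_review"",""days"":8}",printed (acute wards)
polypharmacy-10,regular_med_count_ge,"{""count"":10}",printed
swallowing-difficulties,flag_present,"{""flag"":""swallowing_difficulty""}",printed; merged group also covers new difficulties
parkinsons-medications,medication_class_in,"{""classes"":[""antiparkinsonian""]}",printed
anticoagulants-doac,medication_name_in,"{""names"":[""apixaban"",""rivaroxaban"",""edoxaban"",""dabigatran""]}",printed (round-2 wording)
age-over-80,age_compare,"{""op"":""gt"",""value"":80}",printed
warfarin,medication_name_in,"{""names"":[""warfarin""]}",printed
tdm-drugs,medication_name_in,"{""names"":[""phenytoin"",""carbamazepine"",""digoxin"",""theophylline"",""gentamicin"",""vancomycin""]}",printed examples extended
falls-3-months,flag_present,"{""flag"":""fall_past_3_months""}",printed
age-over-70,age_compare,"{""op"":""gt"",""value"":70}",printed (round-2 wording)
seclusion,flag_present,"{""flag"":""seclusion""}",printed
age-under-18,age_compare,"{""op"":""lt"",""value"":18}",printed
age-under-12,age_compare,"{""op"":""lt"",""value"":12}",printed
alcohol-detox-medications,medication_name_in,"{""names"":[""pabrinex"",""chlordiazepoxide""]}",printed
polypharmacy-5,regular_med_count_ge,"{""count"":5}",printed
anticancer-medications,medication_class_in,"{""classes"":[""cytotoxic"",""antineoplastic""]}",printed
electrolytes-out-of-range,flag_present,"{""flag"":""electrolytes_outside_range""}",printed; merged group also covers WBC and haemoglobin
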