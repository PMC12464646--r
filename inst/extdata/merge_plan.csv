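action,id,into,note
merge,ckd-stage-3a,ckd-stage-3b,stated: CKD stages combined into two groups (<=3b)
merge,ckd-stage-5,ckd-stage-4,stated: CKD stages combined into two groups (>3b)
merge,missed-mh-medications,missed-doses,inferred: missed-dose indicators consolidated
merge,missed-doses-high-risk-mh,missed-doses-high-risk,inferred: missed-dose indicators consolidated
merge,new-swallowing-difficulties,swallowing-difficulties,inferred: swallowing-difficulty indicators consolidated
merge,t2t3-renewal-mha,new-t2t3-mha,inferred: Mental Health Act T2/T3 paperwork consolidated
merge,qtc-prolonging-meds,qtc-out-of-range,inferred: QTc-related indicators consolidated
merge,wbc-out-of-range,electrolytes-out-of-range,inferred: out-of-range blood results consolidated
merge,haemoglobin-out-of-range,electrolytes-out-of-range,inferred: out-of-range blood results consolidated
merge,multiple-anxiolytics,more-than-1-hypnotic-prescribed,inferred: duplicated sedative-load indicators consolidated
exclude,clinical-trial-medicines,,inferred: stakeholder exclusion
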