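"concept_id","name","domain","parent_ids","is_hypernym","embedding"
"root_finding","clinical finding","observation","",FALSE,""
"root_analyte","laboratory analyte","measurement","",FALSE,""
"root_dx","diagnosis concept","condition","",FALSE,""
"root_rx","drug concept","drug","",FALSE,""
"root_proc","procedure concept","procedure","",FALSE,""
"hyp_abnormal_kidney_function","abnormal kidney function","observation","root_finding",TRUE,""
"lf_decreased_egfr","decreased estimated glomerular filtration rate","observation","hyp_abnormal_kidney_function",FALSE,"1.00;0.05;0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00"
"lf_elevated_acr","elevated urine albumin-to-creatinine ratio","observation","hyp_abnormal_kidney_function",FALSE,"1.0;0.1;0.0;0.0;0.0;0.0;0.0;0.0;0.0;0.0;0.0"
"lf_elevated_creatinine","elevated serum creatinine","observation","hyp_abnormal_kidney_function",FALSE,"1.00;0.15;0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00"
"lf_egfr_g3b","estimated glomerular filtration rate at g3b stage","observation","hyp_abnormal_kidney_function",FALSE,"1.0;0.2;0.0;0.0;0.0;0.0;0.0;0.0;0.0;0.0;0.0"
"hyp_abnormal_blood_potassium","abnormal blood potassium","observation","root_finding",TRUE,""
"lf_hyperkalemia_finding","hyperkalemia","observation","hyp_abnormal_blood_potassium",FALSE,"0.00;1.00;0.05;0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00"
"lf_high_potassium_result","elevated blood potassium result","observation","hyp_abnormal_blood_potassium",FALSE,"0.0;1.0;0.1;0.0;0.0;0.0;0.0;0.0;0.0;0.0;0.0"
"lf_potassium_binder_use","potassium binder prescription","observation","hyp_abnormal_blood_potassium",FALSE,"0.00;1.00;0.15;0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00"
"hyp_abnormal_blood_glucose","abnormal blood glucose","observation","root_finding",TRUE,""
"lf_high_glucose_result","elevated blood glucose result","observation","hyp_abnormal_blood_glucose",FALSE,"0.00;0.00;1.00;0.05;0.00;0.00;0.00;0.00;0.00;0.00;0.00"
"hyp_diabetes","diabetes","condition","root_finding",TRUE,""
"lf_t2dm_diagnosis","type 2 diabetes mellitus diagnosis","condition","hyp_diabetes",FALSE,"0.00;0.00;0.00;1.00;0.05;0.00;0.00;0.00;0.00;0.00;0.00"
"hyp_hypertension","hypertension","condition","root_finding",TRUE,""
"lf_htn_diagnosis","essential hypertension diagnosis","condition","hyp_hypertension",FALSE,"0.00;0.00;0.00;0.00;1.00;0.05;0.00;0.00;0.00;0.00;0.00"
"hyp_cardiovascular_disease","cardiovascular disease","condition","root_finding",TRUE,""
"lf_cvd_diagnosis","cardiovascular disease diagnosis","condition","hyp_cardiovascular_disease",FALSE,"0.00;0.00;0.00;0.00;0.00;1.00;0.05;0.00;0.00;0.00;0.00"
"hyp_hyperlipidemia","hyperlipidemia","condition","root_finding",TRUE,""
"lf_hld_diagnosis","hyperlipidemia diagnosis","condition","hyp_hyperlipidemia",FALSE,"0.00;0.00;0.00;0.00;0.00;0.00;1.00;0.05;0.00;0.00;0.00"
"hyp_aki_history","history of acute kidney injury","condition","root_finding",TRUE,""
"lf_aki_diagnosis","acute kidney injury diagnosis","condition","hyp_aki_history",FALSE,"0.00;0.00;0.00;0.00;0.00;0.00;0.00;1.00;0.05;0.00;0.00"
"hyp_elevated_bun","elevated blood urea nitrogen","observation","root_finding",TRUE,""
"lf_high_bun_result","elevated blood urea nitrogen result","observation","hyp_elevated_bun",FALSE,"0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00;1.00;0.05;0.00"
"hyp_elevated_uric_acid","elevated uric acid","observation","root_finding",TRUE,""
"lf_high_ua_result","elevated uric acid result","observation","hyp_elevated_uric_acid",FALSE,"0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00;1.00;0.05"
"hyp_urinary_protein","urinary protein","observation","root_finding",TRUE,""
"lf_urinary_protein","urinary protein present","observation","hyp_urinary_protein",FALSE,"0.05;0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00;0.00;1.00"
"meas_egfr","estimated glomerular filtration rate","measurement","root_analyte",FALSE,""
"meas_acr","urine albumin-to-creatinine ratio","measurement","root_analyte",FALSE,""
"meas_scr","serum creatinine","measurement","root_analyte",FALSE,""
"meas_bun","blood urea nitrogen","measurement","root_analyte",FALSE,""
"meas_ua","uric acid","measurement","root_analyte",FALSE,""
"meas_k","blood potassium","measurement","root_analyte",FALSE,""
"meas_glu","blood glucose","measurement","root_analyte",FALSE,""
"dx_t2dm","type 2 diabetes mellitus","condition","root_dx",FALSE,""
"dx_htn","essential hypertension","condition","root_dx",FALSE,""
"dx_cvd","cardiovascular disease","condition","root_dx",FALSE,""
"dx_hld","hyperlipidemia","condition","root_dx",FALSE,""
"dx_aki","acute kidney injury","condition","root_dx",FALSE,""
"dx_hyperkalemia","hyperkalemia","condition","root_dx",FALSE,""
"dx_proteinuria","proteinuria","condition","root_dx",FALSE,""
"dx_ckd","chronic kidney disease","condition","root_dx",FALSE,""
"dx_glomerulonephritis","glomerulonephritis","condition","root_dx",FALSE,""
"rx_k_binder","potassium binder","drug","root_rx",FALSE,""
"rx_antihypertensive","antihypertensive agent","drug","root_rx",FALSE,""
"proc_ct_scan","computed tomography scan","procedure","root_proc",FALSE,""
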