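rules:
- event_kind: measurement
  concept_id: meas_egfr
  finding_concept_id: lf_decreased_egfr
  comparator: <
  threshold: 60.0
  unit: mL/min
  emit_negative: yes
- event_kind: measurement
  concept_id: meas_acr
  finding_concept_id: lf_elevated_acr
  comparator: '>'
  threshold: 30.0
  unit: mg/g
  emit_negative: no
- event_kind: measurement
  concept_id: meas_scr
  finding_concept_id: lf_elevated_creatinine
  comparator: '>'
  threshold: 115.0
  unit: umol/L
  emit_negative: no
- event_kind: measurement
  concept_id: meas_k
  finding_concept_id: lf_high_potassium_result
  comparator: '>'
  threshold: 5.5
  unit: mmol/L
  emit_negative: no
- event_kind: measurement
  concept_id: meas_glu
  finding_concept_id: lf_high_glucose_result
  comparator: '>'
  threshold: 11.1
  unit: mmol/L
  emit_negative: no
- event_kind: measurement
  concept_id: meas_bun
  finding_concept_id: lf_high_bun_result
  comparator: '>'
  threshold: 9.5
  unit: mmol/L
  emit_negative: no
- event_kind: measurement
  concept_id: meas_ua
  finding_concept_id: lf_high_ua_result
  comparator: '>'
  threshold: 420.0
  unit: umol/L
  emit_negative: no
- event_kind: diagnosis
  concept_id: dx_t2dm
  finding_concept_id: lf_t2dm_diagnosis
- event_kind: diagnosis
  concept_id: dx_htn
  finding_concept_id: lf_htn_diagnosis
- event_kind: diagnosis
  concept_id: dx_cvd
  finding_concept_id: lf_cvd_diagnosis
- event_kind: diagnosis
  concept_id: dx_hld
  finding_concept_id: lf_hld_diagnosis
- event_kind: diagnosis
  concept_id: dx_aki
  finding_concept_id: lf_aki_diagnosis
- event_kind: diagnosis
  concept_id: dx_hyperkalemia
  finding_concept_id: lf_hyperkalemia_finding
- event_kind: diagnosis
  concept_id: dx_proteinuria
  finding_concept_id: lf_urinary_protein
- event_kind: drug
  concept_id: rx_k_binder
  finding_concept_id: lf_potassium_binder_use
kidney_finding_concepts:
- lf_decreased_egfr
- lf_elevated_acr
- lf_elevated_creatinine
- lf_egfr_g3b
kidney_analyte_concepts:
- meas_egfr
- meas_acr
- meas_scr
kidney_disease_dx_concepts:
- dx_ckd
- dx_glomerulonephritis
nephrology_departments: nephrology
risk_hypernyms:
- hyp_aki_history
- hyp_elevated_bun
- hyp_elevated_uric_acid
- hyp_urinary_protein
- hyp_diabetes
- hyp_hypertension
- hyp_cardiovascular_disease
- hyp_hyperlipidemia
- hyp_abnormal_blood_potassium
- hyp_abnormal_blood_glucose
window_days: 90.0
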