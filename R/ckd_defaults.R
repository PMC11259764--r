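# Default CKD vocabulary and rule set.
#
# The shipped concept hierarchy covers the CKD screening application: kidney
# function, the comorbidity/risk concepts clinicians review alongside it
# (AKI history, BUN, uric acid, urinary protein, diabetes, hypertension,
# cardiovascular disease, hyperlipidemia, blood potassium, blood glucose),
# and the raw event concepts (analytes, diagnoses, drugs, procedures) that
# EHR records reference. Hypernym designation stands in for the expert-review
# step: curated generalizations are vocabulary data, not computation.

#' Default CKD concept vocabulary
#'
#' Builds the concept graph used by the CKD screening application. Finding
#' leaves sit under eleven hypernym concepts; event-level concepts (analytes,
#' diagnoses, drugs, procedures) are leaves under per-domain roots and never
#' appear in exported findings. Leaf embeddings are synthetic fixed vectors:
#' leaves under one hypernym share a dominant direction so their pairwise
#' cosine similarity is high, emulating an embedding space in which curated
#' subtrees cohere.
#'
#' @return a `concept_graph`.
#' @export
default_ckd_vocabulary <- function() {
  rows <- list()
  add <- function(id, name, domain, parents = "", hyp = FALSE)
    rows[[length(rows) + 1]] <<- data.frame(concept_id = id, name = name,
                                            domain = domain, parent_ids = parents,
                                            is_hypernym = hyp, stringsAsFactors = FALSE)
  add("root_finding", "clinical finding", "observation")
  add("root_analyte", "laboratory analyte", "measurement")
  add("root_dx", "diagnosis concept", "condition")
  add("root_rx", "drug concept", "drug")
  add("root_proc", "procedure concept", "procedure")

  # hypernym layer (children of root_finding) and its finding leaves
  hyp <- list(
    hyp_abnormal_kidney_function = list(
      name = "abnormal kidney function", domain = "observation",
      leaves = c(lf_decreased_egfr = "decreased estimated glomerular filtration rate",
                 lf_elevated_acr = "elevated urine albumin-to-creatinine ratio",
                 lf_elevated_creatinine = "elevated serum creatinine",
                 lf_egfr_g3b = "estimated glomerular filtration rate at g3b stage")),
    hyp_abnormal_blood_potassium = list(
      name = "abnormal blood potassium", domain = "observation",
      leaves = c(lf_hyperkalemia_finding = "hyperkalemia",
                 lf_high_potassium_result = "elevated blood potassium result",
                 lf_potassium_binder_use = "potassium binder prescription")),
    hyp_abnormal_blood_glucose = list(
      name = "abnormal blood glucose", domain = "observation",
      leaves = c(lf_high_glucose_result = "elevated blood glucose result")),
    hyp_diabetes = list(
      name = "diabetes", domain = "condition",
      leaves = c(lf_t2dm_diagnosis = "type 2 diabetes mellitus diagnosis")),
    hyp_hypertension = list(
      name = "hypertension", domain = "condition",
      leaves = c(lf_htn_diagnosis = "essential hypertension diagnosis")),
    hyp_cardiovascular_disease = list(
      name = "cardiovascular disease", domain = "condition",
      leaves = c(lf_cvd_diagnosis = "cardiovascular disease diagnosis")),
    hyp_hyperlipidemia = list(
      name = "hyperlipidemia", domain = "condition",
      leaves = c(lf_hld_diagnosis = "hyperlipidemia diagnosis")),
    hyp_aki_history = list(
      name = "history of acute kidney injury", domain = "condition",
      leaves = c(lf_aki_diagnosis = "acute kidney injury diagnosis")),
    hyp_elevated_bun = list(
      name = "elevated blood urea nitrogen", domain = "observation",
      leaves = c(lf_high_bun_result = "elevated blood urea nitrogen result")),
    hyp_elevated_uric_acid = list(
      name = "elevated uric acid", domain = "observation",
      leaves = c(lf_high_ua_result = "elevated uric acid result")),
    hyp_urinary_protein = list(
      name = "urinary protein", domain = "observation",
      leaves = c(lf_urinary_protein = "urinary protein present")))

  emb <- list()
  dims <- length(hyp)
  for (k in seq_along(hyp)) {
    hid <- names(hyp)[[k]]
    info <- hyp[[k]]
    add(hid, info$name, info$domain, "root_finding", hyp = TRUE)
    leaves <- info$leaves
    for (j in seq_along(leaves)) {
      lid <- names(leaves)[[j]]
      add(lid, leaves[[j]], info$domain, hid)
      # dominant coordinate per hypernym cluster + small per-leaf offset:
      # within-cluster cosine > 0.9, across-cluster near 0
      v <- numeric(dims)
      v[k] <- 1
      v[(k %% dims) + 1] <- 0.05 * j
      emb[[lid]] <- v
    }
  }

  analytes <- c(meas_egfr = "estimated glomerular filtration rate",
                meas_acr = "urine albumin-to-creatinine ratio",
                meas_scr = "serum creatinine",
                meas_bun = "blood urea nitrogen",
                meas_ua = "uric acid",
                meas_k = "blood potassium",
                meas_glu = "blood glucose")
  for (id in names(analytes)) add(id, analytes[[id]], "measurement", "root_analyte")

  dxs <- c(dx_t2dm = "type 2 diabetes mellitus",
           dx_htn = "essential hypertension",
           dx_cvd = "cardiovascular disease",
           dx_hld = "hyperlipidemia",
           dx_aki = "acute kidney injury",
           dx_hyperkalemia = "hyperkalemia",
           dx_proteinuria = "proteinuria",
           dx_ckd = "chronic kidney disease",
           dx_glomerulonephritis = "glomerulonephritis")
  for (id in names(dxs)) add(id, dxs[[id]], "condition", "root_dx")

  add("rx_k_binder", "potassium binder", "drug", "root_rx")
  add("rx_antihypertensive", "antihypertensive agent", "drug", "root_rx")
  add("proc_ct_scan", "computed tomography scan", "procedure", "root_proc")

  concept_graph(do.call(rbind, rows), embeddings = emb)
}

#' Default CKD screening rule set
#'
#' Measurement thresholds follow the cohort criteria (eGFR strictly below
#' 60 mL/min, ACR strictly above 30 mg/g) and common laboratory reference
#' limits for the remaining analytes; diagnosis and drug rules map recorded
#' events to finding leaves. A normal eGFR result (>= 60) additionally emits a
#' negative kidney-function finding, the recovery marker that can reset the
#' chronicity chain.
#'
#' @param window_days chronicity window in days (default 90 = 3 months,
#'   inclusive comparison).
#' @return object of class `rule_set`.
#' @export
default_ckd_ruleset <- function(window_days = 90) {
  measurement_rules <- data.frame(
    concept_id = c("meas_egfr", "meas_acr", "meas_scr", "meas_k", "meas_glu",
                   "meas_bun", "meas_ua"),
    comparator = c("<", ">", ">", ">", ">", ">", ">"),
    threshold = c(60, 30, 115, 5.5, 11.1, 9.5, 420),
    unit = c("mL/min", "mg/g", "umol/L", "mmol/L", "mmol/L", "mmol/L", "umol/L"),
    finding_concept_id = c("lf_decreased_egfr", "lf_elevated_acr",
                           "lf_elevated_creatinine", "lf_high_potassium_result",
                           "lf_high_glucose_result", "lf_high_bun_result",
                           "lf_high_ua_result"),
    emit_negative = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  diagnosis_rules <- data.frame(
    concept_id = c("dx_t2dm", "dx_htn", "dx_cvd", "dx_hld", "dx_aki",
                   "dx_hyperkalemia", "dx_proteinuria"),
    finding_concept_id = c("lf_t2dm_diagnosis", "lf_htn_diagnosis",
                           "lf_cvd_diagnosis", "lf_hld_diagnosis",
                           "lf_aki_diagnosis", "lf_hyperkalemia_finding",
                           "lf_urinary_protein"),
    stringsAsFactors = FALSE)
  drug_rules <- data.frame(concept_id = "rx_k_binder",
                           finding_concept_id = "lf_potassium_binder_use",
                           stringsAsFactors = FALSE)
  rule_set(measurement_rules, diagnosis_rules, drug_rules,
           kidney_finding_concepts = c("lf_decreased_egfr", "lf_elevated_acr",
                                       "lf_elevated_creatinine", "lf_egfr_g3b"),
           kidney_analyte_concepts = c("meas_egfr", "meas_acr", "meas_scr"),
           kidney_disease_dx_concepts = c("dx_ckd", "dx_glomerulonephritis"),
           nephrology_departments = "nephrology",
           risk_hypernyms = c("hyp_aki_history", "hyp_elevated_bun",
                              "hyp_elevated_uric_acid", "hyp_urinary_protein",
                              "hyp_diabetes", "hyp_hypertension",
                              "hyp_cardiovascular_disease", "hyp_hyperlipidemia",
                              "hyp_abnormal_blood_potassium",
                              "hyp_abnormal_blood_glucose"),
           window_days = window_days)
}
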