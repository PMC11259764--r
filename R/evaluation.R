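# Evaluation of a collaborative run: discovery lead time, risk coverage,
# duplicate-examination reduction, and detection quality against synthetic
# ground truth. On synthetic data the single-hospital diagnosis date comes
# from the planted ground truth; clinical confirmation rates from chart
# review are intentionally out of scope.

#' Identity digests for a ground-truth table
#'
#' @param truth ground-truth data.frame from [generate_consortium()].
#' @param salt,salt_id consortium salt and label.
#' @return named character vector digest -> identity is reversed: names are
#'   identities, values digests.
#' @export
truth_digests <- function(truth, salt, salt_id = "consortium") {
  stats::setNames(hash_identity(normalize_identity(truth$identity), salt, salt_id)$digest,
                  truth$identity)
}

#' Discovery lead time for one detected patient
#'
#' For the multicenter group the lead time is the gap between the date the
#' merged findings met the chronicity criteria and the date single-hospital
#' assessment would diagnose (`t_diagnosis - t_CDS`); for the transferred
#' group it is anchored at the first post-transfer visit
#' (`t_diagnosis - t_transfer`).
#'
#' @param result a `cds_result` with `ckd_met = TRUE`.
#' @param t_diagnosis Date of single-hospital diagnosis (ground truth on
#'   synthetic data).
#' @param t_transfer Date of the first visit to the transferred hospital
#'   (required for the transferred group).
#' @return list: `group`, `t_cds`, `t_diagnosis`, `t_transfer`, `lead_days`.
#' @export
lead_time <- function(result, t_diagnosis, t_transfer = as.Date(NA)) {
  abort_if(!isTRUE(result$ckd_met), "lead time is defined for detected patients only")
  if (is.na(t_diagnosis)) {
    warning("missing t_diagnosis; record skipped")
    return(NULL)
  }
  ld <- if (identical(result$group, "transferred")) {
    abort_if(is.na(t_transfer), "transferred group needs t_transfer")
    as.integer(t_diagnosis - t_transfer)
  } else {
    as.integer(t_diagnosis - result$first_met_date)
  }
  list(digest = result$digest, group = result$group, t_cds = result$first_met_date,
       t_diagnosis = t_diagnosis, t_transfer = t_transfer, lead_days = ld)
}

#' Lead-time records and aggregates for a full run
#'
#' @param run a `collab_run`.
#' @param truth ground-truth table.
#' @param salt,salt_id consortium salt and label.
#' @return list with `records` (data.frame) and `aggregate` (mean, SD, median
#'   of lead days per group).
#' @export
lead_time_table <- function(run, truth, salt, salt_id = "consortium") {
  dig <- truth_digests(truth, salt, salt_id)
  idx <- stats::setNames(seq_len(nrow(truth)), unname(dig))
  recs <- list()
  for (res in run$results) {
    if (!isTRUE(res$ckd_met)) next
    i <- idx[[res$digest]] %||% NA_integer_
    if (is.na(i) || is.na(truth$diagnosis_date[[i]])) next
    r <- lead_time(res, truth$diagnosis_date[[i]], truth$transfer_date[[i]])
    if (!is.null(r)) recs[[length(recs) + 1]] <- as.data.frame(r, stringsAsFactors = FALSE)
  }
  records <- if (length(recs) == 0) {
    data.frame(digest = character(0), group = character(0),
               lead_days = integer(0), stringsAsFactors = FALSE)
  } else reset_rownames(do.call(rbind, recs))
  agg <- if (nrow(records) == 0) {
    data.frame(group = character(0), n = integer(0), mean = numeric(0),
               sd = numeric(0), median = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(split(records, records$group), function(g)
      data.frame(group = g$group[[1]], n = nrow(g), mean = mean(g$lead_days),
                 sd = stats::sd(g$lead_days), median = stats::median(g$lead_days),
                 stringsAsFactors = FALSE)))
  }
  list(records = records, aggregate = reset_rownames(agg))
}

#' CKD-related risk coverage for one detected patient
#'
#' Compares the risk set surfaced by collaborative reasoning within the
#' 3-month window anchored at the ROI end against the baseline a
#' single-hospital review would see: risks derivable from the sponsor's own
#' store within the patient's latest 3 months there. Reported as
#' `100 * |multicenter| / |single|`; undefined (NA) when the baseline set is
#' empty.
#'
#' @param result a `cds_result` with an ROI.
#' @param sponsor_store the sponsor's `ehr_store`.
#' @param rules a `rule_set`.
#' @param map a `hypernym_map`.
#' @param window_days comparison window (default 90).
#' @return list: `risks_multicenter`, `risks_single` (character vectors of
#'   hypernym ids), `cov_percent`.
#' @export
risk_coverage <- function(result, sponsor_store, rules, map, window_days = 90) {
  abort_if(is.null(result$roi), "risk coverage needs an ROI")
  lo <- result$roi$end - window_days
  multi <- unique(result$risks$concept_id[result$risks$date >= lo &
                                            result$risks$date <= result$roi$end])
  single <- character(0)
  p <- result$local_person_id
  if (!is.na(p)) {
    vis <- sponsor_store$visits[sponsor_store$visits$person_id == p, , drop = FALSE]
    if (nrow(vis) > 0) {
      latest <- max(vis$visit_date)
      f <- derive_findings_events(
        sponsor_store$events[sponsor_store$events$visit_id %in% vis$visit_id, , drop = FALSE],
        sponsor_store$visits, rules)
      f <- f[f$positive & f$date >= latest - window_days & f$date <= latest, , drop = FALSE]
      hyp <- unname(map$entries[f$concept_id])
      single <- unique(hyp[!is.na(hyp) & hyp %in% rules$risk_hypernyms])
    }
  }
  cov <- if (length(single) == 0) NA_real_ else 100 * length(multi) / length(single)
  list(risks_multicenter = sort(multi), risks_single = sort(single), cov_percent = cov)
}

#' Duplicate-examination reduction for one detected patient
#'
#' Counts kidney-function test records held at non-sponsor hospitals within
#' the ROI that a single-hospital assessment would have to re-order: remote
#' tests not mirrored by a sponsor-side kidney test within `mirror_days`.
#'
#' @param result a `cds_result` with an ROI.
#' @param stores named list of all `ehr_store`.
#' @param sponsor sponsoring hospital id.
#' @param rules a `rule_set`.
#' @param salt,salt_id consortium salt and label.
#' @param mirror_days mirroring tolerance in days (default 14, closed
#'   interval).
#' @return list: `avoided_tests` (count), `remote_tests`, `mirrored`.
#' @export
duplicate_exam_reduction <- function(result, stores, sponsor, rules, salt,
                                     salt_id = "consortium", mirror_days = 14) {
  abort_if(is.null(result$roi), "duplicate-exam reduction needs an ROI")
  kidney_test_dates <- function(store) {
    digests <- store_digests(store, salt, salt_id)
    pid <- names(digests)[unname(digests) == result$digest]
    if (length(pid) == 0) return(as.Date(character(0)))
    vis <- store$visits$visit_id[store$visits$person_id %in% pid]
    ev <- store$events
    sel <- ev$visit_id %in% vis & ev$kind == "measurement" &
      ev$concept_id %in% rules$kidney_analyte_concepts
    ev$event_date[sel]
  }
  local_dates <- kidney_test_dates(stores[[sponsor]])
  remote <- unlist(lapply(setdiff(names(stores), sponsor), function(h) {
    d <- kidney_test_dates(stores[[h]])
    as.integer(d[d >= result$roi$start & d <= result$roi$end])
  }))
  mirrored <- vapply(remote, function(d)
    any(abs(as.integer(local_dates) - d) <= mirror_days), logical(1))
  list(avoided_tests = sum(!mirrored), remote_tests = length(remote),
       mirrored = sum(mirrored))
}

#' Detection-quality metrics against synthetic ground truth
#'
#' Joins per-patient CDS results to the planted phenotypes and reports
#' sensitivity over planted positives, specificity over negatives (controls,
#' recovery confounders, excluded decoys), PPV, and group-label accuracy.
#' Recovery confounders are tabulated separately: they are the designed
#' false-positive pressure on the recovery-reset rule.
#'
#' @param run a `collab_run`.
#' @param truth ground-truth table.
#' @param salt,salt_id consortium salt and label.
#' @return list with `by_phenotype` (data.frame: planted, detected,
#'   correct_group), `sensitivity`, `specificity`, `ppv`, `group_accuracy`.
#' @export
detection_metrics <- function(run, truth, salt, salt_id = "consortium") {
  dig <- unname(truth_digests(truth, salt, salt_id))
  met <- vapply(run$results, `[[`, logical(1), "ckd_met")
  flagged <- names(run$results)[met]
  groups <- vapply(run$results[met], `[[`, character(1), "group")
  expected_group <- c(multicenter_ckd = "multicenter_data",
                      transferred_ckd = "transferred")
  by_ph <- do.call(rbind, lapply(unique(truth$phenotype), function(ph) {
    d_ph <- dig[truth$phenotype == ph]
    det <- intersect(d_ph, flagged)
    correct <- if (ph %in% names(expected_group))
      sum(groups[det] == expected_group[[ph]]) else NA_integer_
    data.frame(phenotype = ph, planted = length(d_ph), detected = length(det),
               correct_group = correct, stringsAsFactors = FALSE)
  }))
  pos <- dig[truth$phenotype %in% names(expected_group)]
  neg <- dig[!truth$phenotype %in% names(expected_group)]
  tp <- length(intersect(pos, flagged)); fn <- length(setdiff(pos, flagged))
  fp <- length(intersect(neg, flagged)); tn <- length(setdiff(neg, flagged))
  det_pos <- intersect(pos, flagged)
  exp_g <- expected_group[truth$phenotype[match(det_pos, dig)]]
  list(by_phenotype = reset_rownames(by_ph),
       sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       group_accuracy = if (length(det_pos) == 0) NA_real_ else
         mean(groups[det_pos] == unname(exp_g)))
}
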