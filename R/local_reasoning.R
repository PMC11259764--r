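# Rule-based local reasoning over one hospital's store: eligibility screening,
# per-visit atomic findings, hypernym abstraction, and chronicity detection.

#' Construct a reasoning rule set
#'
#' @param measurement_rules data.frame: `concept_id`, `comparator` (`<` or
#'   `>`, strict), `threshold`, `unit`, `finding_concept_id`, `emit_negative`
#'   (emit a negative finding when the rule does not fire — the recovery
#'   marker channel).
#' @param diagnosis_rules,drug_rules,procedure_rules data.frames mapping event
#'   `concept_id` to `finding_concept_id`.
#' @param kidney_finding_concepts finding leaves counted as abnormal kidney
#'   function for the chronicity criteria.
#' @param kidney_analyte_concepts measurement concepts that count as kidney
#'   function tests for cohort eligibility.
#' @param kidney_disease_dx_concepts diagnosis concepts that exclude a patient
#'   (kidney disease already on record).
#' @param nephrology_departments department names that exclude a patient.
#' @param risk_hypernyms hypernym concepts reported as CKD-related risks.
#' @param window_days chronicity window (days, inclusive).
#' @return object of class `rule_set`.
#' @export
rule_set <- function(measurement_rules, diagnosis_rules, drug_rules,
                     procedure_rules = NULL,
                     kidney_finding_concepts = character(0),
                     kidney_analyte_concepts = character(0),
                     kidney_disease_dx_concepts = character(0),
                     nephrology_departments = "nephrology",
                     risk_hypernyms = character(0),
                     window_days = 90) {
  abort_if(!all(measurement_rules$comparator %in% c("<", ">")),
           "measurement comparator must be '<' or '>'")
  abort_if(any(is.na(measurement_rules$unit) | !nzchar(measurement_rules$unit)),
           "measurement thresholds must carry units")
  if (is.null(measurement_rules$emit_negative))
    measurement_rules$emit_negative <- FALSE
  if (is.null(procedure_rules))
    procedure_rules <- data.frame(concept_id = character(0),
                                  finding_concept_id = character(0),
                                  stringsAsFactors = FALSE)
  structure(list(measurement_rules = measurement_rules,
                 diagnosis_rules = diagnosis_rules,
                 drug_rules = drug_rules,
                 procedure_rules = procedure_rules,
                 kidney_finding_concepts = kidney_finding_concepts,
                 kidney_analyte_concepts = kidney_analyte_concepts,
                 kidney_disease_dx_concepts = kidney_disease_dx_concepts,
                 nephrology_departments = nephrology_departments,
                 risk_hypernyms = risk_hypernyms,
                 window_days = window_days),
            class = "rule_set")
}

#' Read a rule set from YAML
#'
#' The YAML layout mirrors [rule_set()]: a `rules` list of
#' `{event_kind, concept_id, comparator, threshold, unit, finding_concept_id,
#' emit_negative}` entries plus top-level keys for the kidney concept sets,
#' department exclusions, risk hypernyms and `window_days`.
#'
#' @param path YAML file.
#' @return a `rule_set`.
#' @export
read_ruleset <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- do.call(rbind, lapply(y$rules, function(r)
    data.frame(event_kind = r$event_kind, concept_id = r$concept_id,
               comparator = r$comparator %||% NA_character_,
               threshold = r$threshold %||% NA_real_,
               unit = r$unit %||% NA_character_,
               finding_concept_id = r$finding_concept_id,
               emit_negative = isTRUE(r$emit_negative),
               stringsAsFactors = FALSE)))
  pick <- function(kind, cols) {
    df <- rules[rules$event_kind == kind, cols, drop = FALSE]
    reset_rownames(df)
  }
  rule_set(
    measurement_rules = pick("measurement", c("concept_id", "comparator", "threshold",
                                              "unit", "finding_concept_id", "emit_negative")),
    diagnosis_rules = pick("diagnosis", c("concept_id", "finding_concept_id")),
    drug_rules = pick("drug", c("concept_id", "finding_concept_id")),
    procedure_rules = pick("procedure", c("concept_id", "finding_concept_id")),
    kidney_finding_concepts = unlist(y$kidney_finding_concepts) %||% character(0),
    kidney_analyte_concepts = unlist(y$kidney_analyte_concepts) %||% character(0),
    kidney_disease_dx_concepts = unlist(y$kidney_disease_dx_concepts) %||% character(0),
    nephrology_departments = unlist(y$nephrology_departments) %||% "nephrology",
    risk_hypernyms = unlist(y$risk_hypernyms) %||% character(0),
    window_days = y$window_days %||% 90)
}

#' Write a rule set to YAML
#' @param rules a `rule_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(rules, path) {
  row_list <- function(df, kind, meas = FALSE) {
    lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      out <- list(event_kind = kind, concept_id = r$concept_id,
                  finding_concept_id = r$finding_concept_id)
      if (meas) out <- c(out, list(comparator = r$comparator, threshold = r$threshold,
                                   unit = r$unit, emit_negative = r$emit_negative))
      out
    })
  }
  yaml::write_yaml(list(
    rules = c(row_list(rules$measurement_rules, "measurement", meas = TRUE),
              row_list(rules$diagnosis_rules, "diagnosis"),
              row_list(rules$drug_rules, "drug"),
              row_list(rules$procedure_rules, "procedure")),
    kidney_finding_concepts = rules$kidney_finding_concepts,
    kidney_analyte_concepts = rules$kidney_analyte_concepts,
    kidney_disease_dx_concepts = rules$kidney_disease_dx_concepts,
    nephrology_departments = rules$nephrology_departments,
    risk_hypernyms = rules$risk_hypernyms,
    window_days = rules$window_days), path)
  invisible(path)
}

#' Cohort eligibility screen for one patient (initiation protocol)
#'
#' A patient enters the collaborative screening cohort at this node iff the
#' node holds at least one kidney-function test result for them, no visit to a
#' nephrology department, and no kidney-disease diagnosis on record. Reason
#' codes enumerate every failed clause.
#'
#' @param store an `ehr_store`.
#' @param person_id patient to screen.
#' @param rules a `rule_set`.
#' @return list with `eligible` (logical) and `reasons` (character vector from
#'   `NO_KIDNEY_TEST`, `NEPHROLOGY_VISIT`, `KIDNEY_DIAGNOSIS`; empty when
#'   eligible).
#' @export
initiation_protocol <- function(store, person_id, rules) {
  abort_if(!person_id %in% store$persons$person_id, "unknown person: ", person_id)
  vis <- store$visits[store$visits$person_id == person_id, , drop = FALSE]
  ev <- store$events[store$events$visit_id %in% vis$visit_id, , drop = FALSE]
  reasons <- character(0)
  if (!any(ev$kind == "measurement" & ev$concept_id %in% rules$kidney_analyte_concepts))
    reasons <- c(reasons, "NO_KIDNEY_TEST")
  if (any(tolower(vis$department) %in% tolower(rules$nephrology_departments)))
    reasons <- c(reasons, "NEPHROLOGY_VISIT")
  if (any(ev$kind == "diagnosis" & ev$concept_id %in% rules$kidney_disease_dx_concepts))
    reasons <- c(reasons, "KIDNEY_DIAGNOSIS")
  list(eligible = length(reasons) == 0, reasons = reasons)
}

# Vectorised store-wide finding derivation. Findings are atomic and per-visit
# local: each row depends only on its own event. Returns one row per fired
# rule, plus negative rows for emit_negative measurement rules that saw the
# analyte in normal range.
derive_findings_events <- function(events, visits, rules) {
  empty <- data.frame(person_id = character(0), visit_id = character(0),
                      date = as.Date(character(0)), concept_id = character(0),
                      positive = logical(0), provenance = character(0),
                      source_event_id = character(0), stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(empty)
  vmap_person <- stats::setNames(visits$person_id, visits$visit_id)
  out <- list(empty)

  m <- events[events$kind == "measurement", , drop = FALSE]
  if (nrow(m) > 0 && nrow(rules$measurement_rules) > 0) {
    mr <- rules$measurement_rules
    idx <- match(m$concept_id, mr$concept_id)
    keep <- !is.na(idx)
    if (any(keep)) {
      m2 <- m[keep, , drop = FALSE]
      r2 <- mr[idx[keep], , drop = FALSE]
      fired <- ifelse(r2$comparator == "<", m2$value < r2$threshold,
                      m2$value > r2$threshold)
      sel <- fired | r2$emit_negative
      if (any(sel)) out[[length(out) + 1]] <- data.frame(
        person_id = unname(vmap_person[m2$visit_id[sel]]),
        visit_id = m2$visit_id[sel], date = m2$event_date[sel],
        concept_id = r2$finding_concept_id[sel], positive = fired[sel],
        provenance = "measurement", source_event_id = m2$event_id[sel],
        stringsAsFactors = FALSE)
    }
  }
  simple <- list(diagnosis = rules$diagnosis_rules, drug = rules$drug_rules,
                 procedure = rules$procedure_rules)
  for (kind in names(simple)) {
    rl <- simple[[kind]]
    e <- events[events$kind == kind, , drop = FALSE]
    if (nrow(e) == 0 || nrow(rl) == 0) next
    idx <- match(e$concept_id, rl$concept_id)
    keep <- !is.na(idx)
    if (!any(keep)) next
    e2 <- e[keep, , drop = FALSE]
    out[[length(out) + 1]] <- data.frame(
      person_id = unname(vmap_person[e2$visit_id]), visit_id = e2$visit_id,
      date = e2$event_date, concept_id = rl$finding_concept_id[idx[keep]],
      positive = TRUE, provenance = kind, source_event_id = e2$event_id,
      stringsAsFactors = FALSE)
  }
  reset_rownames(order_by(do.call(rbind, out),
                          c("person_id", "date", "concept_id", "source_event_id")))
}

#' Derive atomic clinical findings for one visit
#'
#' Applies the rule set to a single visit's events, independently of every
#' other visit (no cross-visit state). Measurement rules fire on strict
#' threshold comparison; `emit_negative` rules also record an explicit
#' negative finding when the analyte is in normal range, which later serves as
#' a recovery marker.
#'
#' @param store an `ehr_store`.
#' @param visit_id visit to analyse.
#' @param rules a `rule_set`.
#' @return data.frame of findings: `person_id`, `visit_id`, `date`,
#'   `concept_id` (leaf), `positive`, `provenance`, `source_event_id`.
#' @export
derive_visit_findings <- function(store, visit_id, rules) {
  abort_if(!visit_id %in% store$visits$visit_id, "unknown visit: ", visit_id)
  ev <- store$events[store$events$visit_id == visit_id, , drop = FALSE]
  derive_findings_events(ev, store$visits, rules)
}

#' Derive findings for every visit in a store
#'
#' Vectorised equivalent of applying [derive_visit_findings()] to each visit.
#'
#' @inheritParams derive_visit_findings
#' @return data.frame of findings (see [derive_visit_findings()]).
#' @export
derive_findings <- function(store, rules) {
  derive_findings_events(store$events, store$visits, rules)
}

#' Abstract leaf findings into privacy-isolated intermediate findings
#'
#' Re-expresses each finding through its hypernym concept and strips value,
#' unit, provenance, raw identity and leaf concept — the privacy contract for
#' anything that leaves a hospital. Findings on the same (person, date,
#' hypernym, label) collapse to one row. Findings whose leaf has no hypernym
#' mapping are dropped with a warning: an unmapped leaf must never be
#' transmitted raw.
#'
#' @param findings data.frame from [derive_findings()].
#' @param map a `hypernym_map`.
#' @param digests named character vector person_id -> hashed identity digest.
#' @return data.frame of intermediate findings: `digest`, `date`,
#'   `hypernym_concept_id`, `positive`.
#' @export
abstract_findings <- function(findings, map, digests) {
  empty <- data.frame(digest = character(0), date = as.Date(character(0)),
                      hypernym_concept_id = character(0), positive = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(findings) == 0) return(empty)
  hyp <- map$entries[findings$concept_id]
  unmapped <- is.na(hyp)
  if (any(unmapped)) {
    warning("dropping ", sum(unmapped), " finding(s) on unmapped leaf concept(s): ",
            paste(unique(findings$concept_id[unmapped]), collapse = ", "))
    findings <- findings[!unmapped, , drop = FALSE]
    hyp <- hyp[!unmapped]
  }
  if (nrow(findings) == 0) return(empty)
  miss <- setdiff(unique(findings$person_id), names(digests))
  abort_if(length(miss) > 0, "no identity digest for person: ", paste(miss, collapse = ", "))
  out <- data.frame(digest = unname(digests[findings$person_id]),
                    date = findings$date, hypernym_concept_id = unname(hyp),
                    positive = findings$positive, stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("digest", "date", "hypernym_concept_id", "positive")]), ,
             drop = FALSE]
  reset_rownames(order_by(out, c("digest", "date", "hypernym_concept_id", "positive")))
}

#' Chronicity verdict over a kidney-function finding timeline
#'
#' The criteria are met iff two abnormal kidney-function findings lie at least
#' `window_days` apart (inclusive) with no normal kidney-function observation
#' dated strictly between them — a normal result in the gap resets the chain,
#' guarding against transient dysfunction. `first_met_date` is the earliest
#' second element over all qualifying pairs, and the returned supporting pair
#' realises it.
#'
#' @param timeline data.frame with columns `date` and `positive` (TRUE =
#'   abnormal kidney-function finding, FALSE = normal observation).
#' @param window_days chronicity window (default 90).
#' @return list: `met` (logical), `first_met_date` (Date or NA), `pair` (Date
#'   vector of the supporting pair, length 2, or NULL).
#' @export
detect_ckd_criteria <- function(timeline, window_days = 90) {
  not_met <- list(met = FALSE, first_met_date = as.Date(NA), pair = NULL)
  if (is.null(timeline) || nrow(timeline) == 0) return(not_met)
  ab <- sort(unique(as.Date(timeline$date[timeline$positive])))
  nrm <- sort(unique(as.Date(timeline$date[!timeline$positive])))
  if (length(ab) < 2) return(not_met)
  for (j in seq_along(ab)[-1]) {
    dj <- ab[[j]]
    before <- nrm[nrm < dj]
    lnb <- if (length(before) > 0) max(before) else as.Date("0001-01-01")
    cand <- ab[ab >= lnb & ab <= dj - window_days]
    if (length(cand) > 0) {
      di <- min(cand)
      return(list(met = TRUE, first_met_date = dj, pair = c(di, dj)))
    }
  }
  not_met
}

#' Chronicity verdict for one patient from a single hospital's store
#'
#' Derives kidney-function findings (abnormal and normal-observation rows)
#' from the store alone and applies [detect_ckd_criteria()]: the
#' single-center-insufficiency check.
#'
#' @param store an `ehr_store`.
#' @param person_id patient.
#' @param rules a `rule_set`.
#' @return as [detect_ckd_criteria()].
#' @export
detect_ckd_single <- function(store, person_id, rules) {
  vis <- store$visits[store$visits$person_id == person_id, , drop = FALSE]
  ev <- store$events[store$events$visit_id %in% vis$visit_id, , drop = FALSE]
  f <- derive_findings_events(ev, store$visits, rules)
  k <- kidney_timeline(f, rules)
  detect_ckd_criteria(k, rules$window_days)
}

# restrict findings to the kidney-function channel: positives on kidney
# finding concepts, plus negative recovery markers on those same concepts
kidney_timeline <- function(findings, rules) {
  sel <- findings$concept_id %in% rules$kidney_finding_concepts
  findings[sel, c("date", "positive"), drop = FALSE]
}
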