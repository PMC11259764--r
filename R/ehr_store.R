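# Per-hospital EHR store: OMOP-lite tables and their semantic projection.
#
# The store holds three collections — persons, visits, events — mirroring the
# OMOP CDM tables person, visit_occurrence and the four event tables
# (condition_occurrence, measurement, drug_exposure, procedure_occurrence).
# Multi-day admissions collapse to a single day-granular visit_date; intervals
# elsewhere in the package are closed on both ends.

EVENT_KINDS <- c("diagnosis", "measurement", "drug", "procedure")

# table file name -> event kind
EVENT_TABLES <- c(condition_occurrence = "diagnosis", measurement = "measurement",
                  drug_exposure = "drug", procedure_occurrence = "procedure")

# mg/mmol -> mg/g for albumin-to-creatinine ratios
ACR_MGMMOL_TO_MGG <- 8.84

#' Construct a validated per-hospital EHR store
#'
#' @param hospital_id opaque hospital identifier (used in resource URIs).
#' @param persons data.frame: `person_id`, `identity` (raw citizen-identity
#'   string, sensitive — never leaves the store un-hashed), `birth_year`, `sex`.
#' @param visits data.frame: `visit_id`, `person_id`, `visit_date`, `department`.
#' @param events data.frame: `event_id`, `visit_id`, `kind` (diagnosis /
#'   measurement / drug / procedure), `concept_id`, `value`, `unit`,
#'   `event_date`. Measurement events must carry value + unit; others must not.
#' @return object of class `ehr_store`.
#' @export
ehr_store <- function(hospital_id, persons, visits, events) {
  persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)

  abort_if(anyDuplicated(persons$person_id) > 0, "duplicate person_id")
  abort_if(anyDuplicated(visits$visit_id) > 0, "duplicate visit_id")
  abort_if(nrow(events) > 0 && anyDuplicated(events$event_id) > 0, "duplicate event_id")
  abort_if(any(!nzchar(persons$identity)), "empty identity string in person table")
  by <- as.integer(persons$birth_year)
  abort_if(anyNA(by) && nrow(persons) > 0 || any(by < 1900 | by > as.integer(format(Sys.Date(), "%Y"))),
           "implausible birth_year in person table")
  abort_if(any(!persons$sex %in% c("female", "male")), "sex must be female/male")

  bad_v <- setdiff(visits$person_id, persons$person_id)
  abort_if(length(bad_v) > 0,
           "visit references missing person: ", paste(utils::head(bad_v, 3), collapse = ", "))
  if (nrow(events) > 0) {
    bad_e <- setdiff(events$visit_id, visits$visit_id)
    abort_if(length(bad_e) > 0,
             "event references missing visit: ", paste(utils::head(bad_e, 3), collapse = ", "))
    abort_if(any(!events$kind %in% EVENT_KINDS), "unknown event kind")
    meas <- events$kind == "measurement"
    abort_if(any(meas & (is.na(events$value) | is.na(events$unit) | !nzchar(events$unit))),
             "measurement events must carry value and unit")
    abort_if(any(!meas & !is.na(events$value)),
             "non-measurement events must not carry a value")
  } else {
    events <- data.frame(event_id = character(0), visit_id = character(0),
                         kind = character(0), concept_id = character(0),
                         value = numeric(0), unit = character(0),
                         event_date = as.Date(character(0)),
                         stringsAsFactors = FALSE)
  }
  visits$visit_date <- as_ymd(visits$visit_date)
  if (nrow(events) > 0) events$event_date <- as_ymd(events$event_date)

  structure(list(hospital_id = hospital_id,
                 persons = reset_rownames(persons),
                 visits = reset_rownames(visits),
                 events = reset_rownames(events)),
            class = "ehr_store")
}

#' @export
print.ehr_store <- function(x, ...) {
  cat(sprintf("<ehr_store %s> %d persons, %d visits, %d events\n",
              x$hospital_id, nrow(x$persons), nrow(x$visits), nrow(x$events)))
  invisible(x)
}

empty_events <- function() {
  data.frame(event_id = character(0), visit_id = character(0), kind = character(0),
             concept_id = character(0), value = numeric(0), unit = character(0),
             event_date = as.Date(character(0)), stringsAsFactors = FALSE)
}

#' Load an OMOP-lite EHR store from a directory of CSV tables
#'
#' Requires `person.csv` and `visit_occurrence.csv`; reads whichever of
#' `condition_occurrence.csv`, `measurement.csv`, `drug_exposure.csv`,
#' `procedure_occurrence.csv` are present (at least one must exist, though it
#' may be empty) into the unified event collection. Albumin-to-creatinine
#' ratios recorded in mg/mmol are converted to mg/g (x 8.84) at load so the
#' reasoning thresholds see a single unit.
#'
#' @param dir directory containing the CSV tables.
#' @param hospital_id hospital identifier; defaults to the directory name.
#' @param acr_concepts concept ids treated as ACR measurements for unit
#'   conversion.
#' @return an `ehr_store`.
#' @export
load_store <- function(dir, hospital_id = basename(normalizePath(dir)),
                       acr_concepts = "meas_acr") {
  need <- file.path(dir, c("person.csv", "visit_occurrence.csv"))
  abort_if(!all(file.exists(need)), "missing required table(s) in ", dir)
  present <- names(EVENT_TABLES)[file.exists(file.path(dir, paste0(names(EVENT_TABLES), ".csv")))]
  abort_if(length(present) == 0, "no event table present in ", dir)

  persons <- utils::read.csv(file.path(dir, "person.csv"),
                             stringsAsFactors = FALSE, colClasses = "character")
  persons$birth_year <- as.integer(persons$birth_year)
  visits <- utils::read.csv(file.path(dir, "visit_occurrence.csv"),
                            stringsAsFactors = FALSE, colClasses = "character")

  evs <- lapply(present, function(tb) {
    df <- utils::read.csv(file.path(dir, paste0(tb, ".csv")),
                          stringsAsFactors = FALSE, colClasses = "character")
    if (nrow(df) == 0) return(empty_events())
    kind <- EVENT_TABLES[[tb]]
    out <- data.frame(event_id = df$event_id, visit_id = df$visit_id,
                      kind = kind, concept_id = df$concept_id,
                      value = NA_real_, unit = NA_character_,
                      event_date = as_ymd(df$event_date), stringsAsFactors = FALSE)
    if (kind == "measurement") {
      out$value <- as.numeric(df$value)
      out$unit <- df$unit
      is_acr <- out$concept_id %in% acr_concepts & out$unit == "mg/mmol"
      out$value[is_acr] <- out$value[is_acr] * ACR_MGMMOL_TO_MGG
      out$unit[is_acr] <- "mg/g"
    }
    out
  })
  events <- do.call(rbind, c(list(empty_events()), evs))
  store <- ehr_store(hospital_id, persons, visits, events)
  message(sprintf("loaded %s: %d persons, %d visits, %d events",
                  hospital_id, nrow(store$persons), nrow(store$visits), nrow(store$events)))
  store
}

#' Write an EHR store to the OMOP-lite CSV layout
#'
#' Emits `person.csv`, `visit_occurrence.csv` and the four event tables
#' (empty ones included) with deterministic row order, so identical stores
#' serialize byte-identically.
#'
#' @param store an `ehr_store`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                                            quote = TRUE, na = "")
  wr(order_by(store$persons, "person_id"), "person.csv")
  v <- order_by(store$visits, "visit_id")
  v$visit_date <- format(v$visit_date)
  wr(v, "visit_occurrence.csv")
  for (tb in names(EVENT_TABLES)) {
    kind <- EVENT_TABLES[[tb]]
    e <- store$events[store$events$kind == kind, , drop = FALSE]
    e <- order_by(e, "event_id")
    out <- data.frame(event_id = e$event_id, visit_id = e$visit_id,
                      concept_id = e$concept_id, event_date = format(e$event_date),
                      stringsAsFactors = FALSE)
    if (kind == "measurement") { out$value <- e$value; out$unit <- e$unit }
    wr(out, paste0(tb, ".csv"))
  }
  invisible(dir)
}

uri <- function(hospital_id, kind, id) {
  if (length(id) == 0) return(character(0))
  paste0(hospital_id, "/", kind, "/", id)
}

#' Project an EHR store into patient-visit-treatment semantic triples
#'
#' Emits an RDF-style triple set under a patient-centric three-level model:
#' one `rdf:type` triple per person; per visit a type triple, a `ehr:hasVisit`
#' edge from its patient and a `ehr:visitDate` literal (3 triples); per event
#' a type triple carrying the event kind, a `ehr:hasEvent` edge from its visit
#' and a `ehr:hasConcept` edge into the vocabulary (3 triples), plus
#' `ehr:hasValue` / `ehr:hasUnit` literals for measurements (2 more). Resource
#' identifiers follow `<hospital_id>/<entity-kind>/<local-id>`.
#'
#' @param store an `ehr_store`.
#' @return data.frame with columns `subject`, `predicate`, `object`.
#' @export
to_triples <- function(store) {
  h <- store$hospital_id
  p_uri <- uri(h, "person", store$persons$person_id)
  tr <- list(data.frame(subject = p_uri, predicate = "rdf:type",
                        object = "ehr:Patient", stringsAsFactors = FALSE))
  if (nrow(store$visits) > 0) {
    v <- store$visits
    v_uri <- uri(h, "visit", v$visit_id)
    tr <- c(tr, list(
      data.frame(subject = v_uri, predicate = "rdf:type", object = "ehr:Visit",
                 stringsAsFactors = FALSE),
      data.frame(subject = uri(h, "person", v$person_id), predicate = "ehr:hasVisit",
                 object = v_uri, stringsAsFactors = FALSE),
      data.frame(subject = v_uri, predicate = "ehr:visitDate",
                 object = paste0('"', format(v$visit_date), '"'), stringsAsFactors = FALSE)))
  }
  if (nrow(store$events) > 0) {
    e <- store$events
    e_uri <- uri(h, "event", e$event_id)
    tr <- c(tr, list(
      data.frame(subject = e_uri, predicate = "rdf:type",
                 object = paste0("ehr:", e$kind), stringsAsFactors = FALSE),
      data.frame(subject = uri(h, "visit", e$visit_id), predicate = "ehr:hasEvent",
                 object = e_uri, stringsAsFactors = FALSE),
      data.frame(subject = e_uri, predicate = "ehr:hasConcept",
                 object = paste0("concept:", e$concept_id), stringsAsFactors = FALSE)))
    m <- e[e$kind == "measurement", , drop = FALSE]
    if (nrow(m) > 0) {
      m_uri <- uri(h, "event", m$event_id)
      tr <- c(tr, list(
        data.frame(subject = m_uri, predicate = "ehr:hasValue",
                   object = paste0('"', format(m$value, trim = TRUE, scientific = FALSE), '"'),
                   stringsAsFactors = FALSE),
        data.frame(subject = m_uri, predicate = "ehr:hasUnit",
                   object = paste0('"', m$unit, '"'), stringsAsFactors = FALSE)))
    }
  }
  reset_rownames(do.call(rbind, tr))
}

#' Canonical serialization of a triple set
#'
#' N-Triples-like lines (`subject predicate object .`) sorted lexicographically,
#' for deterministic diffing across runs.
#'
#' @param triples data.frame from [to_triples()].
#' @return character vector of sorted lines.
#' @export
serialize_triples <- function(triples) {
  sort(sprintf("%s %s %s .", triples$subject, triples$predicate, triples$object),
       method = "radix")
}

#' Ordered visit timeline for one patient
#'
#' Visits sorted ascending by date (ties broken by visit_id); each visit's
#' events sorted by event date then event_id. The result is invariant under
#' permutation of the store's input rows.
#'
#' @param store an `ehr_store`.
#' @param person_id person to extract.
#' @return object of class `patient_timeline`: list with `person_id`,
#'   `hospital_id`, `visits` (ordered data.frame) and `events` (ordered
#'   data.frame carrying `visit_date`).
#' @export
patient_timeline <- function(store, person_id) {
  abort_if(!person_id %in% store$persons$person_id, "unknown person: ", person_id)
  v <- store$visits[store$visits$person_id == person_id, , drop = FALSE]
  v <- reset_rownames(v[order(v$visit_date, v$visit_id), , drop = FALSE])
  e <- store$events[store$events$visit_id %in% v$visit_id, , drop = FALSE]
  e$visit_date <- v$visit_date[match(e$visit_id, v$visit_id)]
  e <- reset_rownames(e[order(e$event_date, e$event_id), , drop = FALSE])
  structure(list(person_id = person_id, hospital_id = store$hospital_id,
                 visits = v, events = e), class = "patient_timeline")
}
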