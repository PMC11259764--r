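# Seeded multi-hospital synthetic cohort generator.
#
# Emulates the study conditions the pipeline targets: longitudinal EHR
# trajectories fragmented across 2-3 hospitals, kidney-function measurement
# series with chronic decline, recovery confounders, non-nephrology department
# visits, and comorbidity diagnoses. Every patient is re-verified against a
# brute-force chronicity oracle before the consortium is returned, so the
# planted phenotype labels are guaranteed, not merely intended.

PHENOTYPES <- c("multicenter_ckd", "transferred_ckd", "recovery_confounder", "control")

DEPARTMENTS <- c("cardiovascular medicine", "emergency", "gastroenterology",
                 "ophthalmology", "orthopedics", "endocrinology", "urology",
                 "respiratory medicine", "cardiology", "infectious disease")

# Table-1-like comorbidity prevalences used for background diagnoses
COMORBIDITY_P <- c(dx_t2dm = 0.135, dx_htn = 0.237, dx_cvd = 0.09, dx_hld = 0.025)

#' Configuration of a synthetic consortium
#'
#' @param n_patients number of cohort patients (decoys come on top).
#' @param n_hospitals number of hospitals (>= 2).
#' @param phenotype_fractions named proportions over `multicenter_ckd`,
#'   `transferred_ckd`, `recovery_confounder`, `control`; must sum to 1.
#' @param study_window length-2 date vector; must span at least 12 months so
#'   90-day chronicity is plantable.
#' @param seed integer RNG seed; the consortium is a pure function of the
#'   config.
#' @param visit_rate mean background visits per patient per year.
#' @param measurement_noise scale factor on analyte noise SDs.
#' @param decoy_fraction fraction of `n_patients` added as exclusion decoys
#'   (nephrology visit or kidney-disease diagnosis on record).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100, n_hospitals = 3,
                          phenotype_fractions = c(multicenter_ckd = 0.15,
                                                  transferred_ckd = 0.15,
                                                  recovery_confounder = 0.10,
                                                  control = 0.60),
                          study_window = c("2016-01-01", "2020-11-30"),
                          seed = 1, visit_rate = 3, measurement_noise = 1,
                          decoy_fraction = 0) {
  abort_if(n_hospitals < 2, "need at least 2 hospitals")
  abort_if(!setequal(names(phenotype_fractions), PHENOTYPES),
           "phenotype_fractions must name exactly: ", paste(PHENOTYPES, collapse = ", "))
  abort_if(abs(sum(phenotype_fractions) - 1) > 1e-8, "phenotype fractions must sum to 1")
  window <- as_ymd(study_window)
  abort_if(as.integer(window[2] - window[1]) < 365,
           "study window must span at least 12 months (chronicity must be plantable)")
  structure(list(n_patients = as.integer(n_patients),
                 n_hospitals = as.integer(n_hospitals),
                 phenotype_fractions = phenotype_fractions[PHENOTYPES],
                 study_window = window, seed = as.integer(seed),
                 visit_rate = visit_rate, measurement_noise = measurement_noise,
                 decoy_fraction = decoy_fraction),
            class = "cohort_config")
}

# one-decimal values with a forced nonzero decimal, so raw values are
# unambiguous byte patterns when scanning serialized payloads for leaks
dec1 <- function(x) {
  x <- round(x, 1)
  ifelse(abs(x - round(x)) < 1e-9, x + 0.1, x)
}

rtrunc <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

# synthetic 18-character citizen-ID-like token: 17 digits + check character
gen_identity <- function() {
  paste0(paste(sample(0:9, 17, replace = TRUE), collapse = ""),
         sample(c(as.character(0:9), "X"), 1))
}

#' Plant a kidney-function trajectory for one phenotype
#'
#' Returns the kidney measurement series (hospital, day offset, eGFR value)
#' realising the phenotype's defining satisfiability pattern:
#' `multicenter_ckd` — abnormal results at two hospitals >= 90 days apart in
#' union but pairwise < 90 days within any one hospital; `transferred_ckd` —
#' two abnormal results >= 90 days apart at one hospital, then a transfer
#' visit elsewhere with no kidney tests; `recovery_confounder` — abnormal,
#' normal, abnormal, so no uninterrupted 90-day chain; `control` — normal
#' values only.
#'
#' @param phenotype one of the four phenotype labels.
#' @param hospitals character vector of hospital ids the patient visits
#'   (>= 2 for the CKD phenotypes).
#' @param span_days length of the study window in days.
#' @return list with `kidney` (data.frame `hospital`, `day`, `value`),
#'   `onset_day`, `transfer_day`, `per_hospital_day` (named integer vector of
#'   single-hospital satisfiability days, NA when never satisfiable).
#' @export
plant_ckd_trajectory <- function(phenotype, hospitals, span_days) {
  abort_if(!phenotype %in% PHENOTYPES, "unknown phenotype: ", phenotype)
  abort_if(phenotype != "control" && length(hospitals) < 2,
           "CKD phenotypes need >= 2 hospitals")
  abn <- function() dec1(stats::runif(1, 30, 55))
  nrm <- function() dec1(stats::runif(1, 65, 105))
  per_h <- stats::setNames(rep(NA_integer_, length(hospitals)), hospitals)
  A <- hospitals[[1]]; B <- if (length(hospitals) > 1) hospitals[[2]] else NA

  if (phenotype == "multicenter_ckd") {
    t0 <- sample.int(max(1L, span_days - 320L), 1) - 1L
    gap <- sample(90:max(90L, min(220L, span_days - t0 - 10L)), 1)
    rows <- data.frame(hospital = c(A, B), day = c(t0, t0 + gap),
                       value = c(abn(), abn()), stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.5) {
      extra <- t0 + sample(20:60, 1)  # < 90 days from t0: A stays unsatisfiable
      rows <- rbind(rows, data.frame(hospital = A, day = extra, value = abn()))
    }
    return(list(kidney = rows, onset_day = t0 + gap, transfer_day = NA_integer_,
                per_hospital_day = per_h))
  }
  if (phenotype == "transferred_ckd") {
    t0 <- sample.int(max(1L, span_days - 420L), 1) - 1L
    gap <- sample(90:max(90L, min(200L, span_days - t0 - 40L)), 1)
    delta <- sample(30:max(30L, min(150L, span_days - t0 - gap)), 1)
    rows <- data.frame(hospital = c(A, A), day = c(t0, t0 + gap),
                       value = c(abn(), abn()), stringsAsFactors = FALSE)
    per_h[[A]] <- t0 + gap
    return(list(kidney = rows, onset_day = t0 + gap,
                transfer_day = t0 + gap + delta, per_hospital_day = per_h))
  }
  if (phenotype == "recovery_confounder") {
    t0 <- sample.int(max(1L, span_days - 260L), 1) - 1L
    rows <- data.frame(hospital = c(A, B, B), day = t0 + c(0L, 60L, 150L),
                       value = c(abn(), nrm(), abn()), stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.5)
      rows <- rbind(rows, data.frame(hospital = A, day = t0 + 210L, value = nrm()))
    return(list(kidney = rows, onset_day = NA_integer_, transfer_day = NA_integer_,
                per_hospital_day = per_h))
  }
  # control: 1-3 normal results spread over the window and hospitals
  k <- sample(1:3, 1)
  rows <- data.frame(hospital = sample(hospitals, k, replace = TRUE),
                     day = sort(sample.int(span_days, k) - 1L),
                     value = dec1(stats::runif(k, 65, 105)), stringsAsFactors = FALSE)
  list(kidney = rows, onset_day = NA_integer_, transfer_day = NA_integer_,
       per_hospital_day = per_h)
}

# brute-force chronicity oracle: O(n^2) over all abnormal pairs with an
# intervening-normal scan; used only to re-verify the generator's output
ckd_brute_oracle <- function(days, abnormal, window = 90) {
  ab <- sort(unique(days[abnormal])); nm <- sort(unique(days[!abnormal]))
  best <- NA_integer_
  for (i in seq_along(ab)) for (j in seq_along(ab)) {
    if (ab[j] - ab[i] >= window && !any(nm > ab[i] & nm < ab[j]))
      best <- min(best, ab[j], na.rm = TRUE)
  }
  list(met = !is.na(best), first_met_day = best)
}

#' Generate a seeded multi-hospital synthetic consortium
#'
#' Builds per-hospital EHR stores plus ground-truth labels. Every patient
#' visits at least two hospitals under the same raw identity (with different
#' local person ids), no single hospital holds all of a patient's visits, and
#' each phenotype's satisfiability pattern is re-verified against the
#' brute-force chronicity oracle before the consortium is returned. Fully
#' deterministic given the config (including its seed).
#'
#' @param config a [cohort_config()].
#' @return object of class `consortium`: list with `stores` (named list of
#'   `ehr_store`), `truth` (ground-truth data.frame), `config`.
#' @export
generate_consortium <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  span <- as.integer(config$study_window[2] - config$study_window[1])
  hosp_ids <- sprintf("H%d", seq_len(config$n_hospitals))

  # largest-remainder apportionment of phenotype counts
  raw <- config$phenotype_fractions * config$n_patients
  counts <- floor(raw)
  rem <- config$n_patients - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  phenos <- rep(names(counts), counts)

  n_decoys <- round(config$decoy_fraction * config$n_patients)
  built <- vector("list", length(phenos) + n_decoys)
  identities <- character(0)
  for (i in seq_along(phenos)) {
    repeat { id <- gen_identity(); if (!id %in% identities) break }
    identities <- c(identities, id)
    built[[i]] <- build_patient(i, id, phenos[[i]], hosp_ids, span, config,
                                decoy = FALSE)
  }
  for (j in seq_len(n_decoys)) {
    i <- length(phenos) + j
    repeat { id <- gen_identity(); if (!id %in% identities) break }
    identities <- c(identities, id)
    built[[i]] <- build_patient(i, id, "multicenter_ckd", hosp_ids, span, config,
                                decoy = TRUE)
  }

  cons <- assemble_consortium(built, hosp_ids, config)
  verify_consortium(cons)
  cons
}

# build one patient: visits/events rows across hospitals + a truth row
build_patient <- function(idx, identity, phenotype, hosp_ids, span, config, decoy) {
  n_h <- sample(2:min(3, length(hosp_ids)), 1)
  if (phenotype == "transferred_ckd" && !decoy) n_h <- 2
  my_hosp <- sample(hosp_ids, n_h)
  traj <- plant_ckd_trajectory(phenotype, my_hosp, span)

  ev <- list()  # rows: hospital, day, kind, concept, value, unit
  add <- function(hospital, day, kind, concept, value = NA_real_, unit = NA_character_)
    ev[[length(ev) + 1]] <<- list(hospital = hospital, day = as.integer(day),
                                  kind = kind, concept = concept,
                                  value = value, unit = unit)
  for (r in seq_len(nrow(traj$kidney)))
    add(traj$kidney$hospital[r], traj$kidney$day[r], "measurement", "meas_egfr",
        traj$kidney$value[r], "mL/min")

  # risk / comorbidity evidence for positives, placed inside the planted window
  if (phenotype %in% c("multicenter_ckd", "transferred_ckd")) {
    roi_lo <- min(traj$kidney$day); roi_hi <- traj$onset_day
    risk_pool <- list(
      list(kind = "diagnosis", concept = "dx_aki"),
      list(kind = "diagnosis", concept = "dx_proteinuria"),
      list(kind = "diagnosis", concept = "dx_t2dm"),
      list(kind = "diagnosis", concept = "dx_htn"),
      list(kind = "diagnosis", concept = "dx_cvd"),
      list(kind = "measurement", concept = "meas_bun", lo = 10, hi = 15, unit = "mmol/L"),
      list(kind = "measurement", concept = "meas_ua", lo = 430, hi = 550, unit = "umol/L"),
      list(kind = "measurement", concept = "meas_k", lo = 5.6, hi = 6.2, unit = "mmol/L"),
      list(kind = "measurement", concept = "meas_glu", lo = 11.5, hi = 15, unit = "mmol/L"))
    risk_hosp <- if (phenotype == "transferred_ckd") my_hosp[[1]] else my_hosp
    for (rk in sample(risk_pool, sample(2:4, 1))) {
      d <- sample(roi_lo:roi_hi, 1)
      h <- if (length(risk_hosp) == 1) risk_hosp else sample(risk_hosp, 1)
      if (rk$kind == "diagnosis") add(h, d, "diagnosis", rk$concept)
      else add(h, d, "measurement", rk$concept, dec1(stats::runif(1, rk$lo, rk$hi)), rk$unit)
    }
  }

  # background comorbidities and benign measurements
  for (dx in names(COMORBIDITY_P)) if (stats::runif(1) < COMORBIDITY_P[[dx]])
    add(sample(my_hosp, 1), sample.int(span, 1) - 1L, "diagnosis", dx)
  nz <- config$measurement_noise
  n_bg <- stats::rpois(1, 2) + 1L
  for (b in seq_len(n_bg)) {
    h <- sample(my_hosp, 1); d <- sample.int(span, 1) - 1L
    pick <- sample(3, 1)
    if (pick == 1) add(h, d, "measurement", "meas_k",
                       dec1(rtrunc(1, 4.27, 0.46 * nz, 3.6, 5.3)), "mmol/L")
    else if (pick == 2) add(h, d, "measurement", "meas_glu",
                            dec1(rtrunc(1, 5.97, 1.92 * nz, 4.0, 9.0)), "mmol/L")
    else add(h, d, "measurement", "meas_scr",
             dec1(rtrunc(1, 85, 15 * nz, 60, 108)), "umol/L")
  }
  # occasional benign drug / procedure records
  if (stats::runif(1) < 0.3)
    add(sample(my_hosp, 1), sample.int(span, 1) - 1L, "drug", "rx_antihypertensive")
  if (stats::runif(1) < 0.2)
    add(sample(my_hosp, 1), sample.int(span, 1) - 1L, "procedure", "proc_ct_scan")

  evdf <- data.frame(hospital = vapply(ev, `[[`, "", "hospital"),
                     day = vapply(ev, `[[`, 0L, "day"),
                     kind = vapply(ev, `[[`, "", "kind"),
                     concept = vapply(ev, `[[`, "", "concept"),
                     value = vapply(ev, `[[`, 0, "value"),
                     unit = vapply(ev, `[[`, "", "unit"),
                     stringsAsFactors = FALSE)

  # transfer visit (no kidney tests) for the transferred phenotype
  extra_visits <- NULL
  if (phenotype == "transferred_ckd" && !decoy) {
    B <- my_hosp[[2]]
    tday <- traj$transfer_day
    later <- unique(c(tday, tday + sort(sample(30:300, sample(0:2, 1)))))
    later <- later[later <= span]
    extra_visits <- data.frame(hospital = B, day = as.integer(later),
                               stringsAsFactors = FALSE)
  }
  # every chosen hospital holds >= 1 visit
  covered <- unique(c(evdf$hospital, extra_visits$hospital))
  for (h in setdiff(my_hosp, covered)) {
    extra_visits <- rbind(extra_visits,
                          data.frame(hospital = h, day = sample.int(span, 1) - 1L,
                                     stringsAsFactors = FALSE))
  }
  # decoys carry the exclusion marker: a nephrology visit or a kidney diagnosis
  decoy_neph <- NULL
  if (decoy) {
    h <- sample(my_hosp, 1)
    if (stats::runif(1) < 0.5) {
      decoy_neph <- data.frame(hospital = h, day = sample.int(span, 1) - 1L,
                               stringsAsFactors = FALSE)
    } else {
      evdf <- rbind(evdf, data.frame(hospital = h, day = sample.int(span, 1) - 1L,
                                     kind = "diagnosis", concept = "dx_ckd",
                                     value = NA_real_, unit = NA_character_,
                                     stringsAsFactors = FALSE))
    }
  }

  list(idx = idx, identity = identity,
       phenotype = if (decoy) "excluded" else phenotype,
       hospitals = my_hosp, events = evdf, extra_visits = extra_visits,
       neph_visits = decoy_neph,
       birth_year = sample(1935:1975, 1), sex = sample(c("female", "male"), 1),
       onset_day = traj$onset_day, transfer_day = traj$transfer_day,
       per_hospital_day = traj$per_hospital_day,
       diagnosis_day = if (!decoy && phenotype %in% c("multicenter_ckd", "transferred_ckd"))
         traj$onset_day + sample(90:700, 1) else NA_integer_)
}

assemble_consortium <- function(built, hosp_ids, config) {
  ws <- config$study_window[1]
  per_h <- stats::setNames(lapply(hosp_ids, function(h)
    list(persons = list(), visits = list(), events = list())), hosp_ids)

  truth_rows <- vector("list", length(built))
  for (b in built) {
    pid_by_h <- stats::setNames(sprintf("%s_p%05d", b$hospitals, b$idx), b$hospitals)
    # visit days per hospital: event days + extra visit days (+ decoy nephrology)
    vis <- rbind(b$events[c("hospital", "day")], b$extra_visits,
                 if (!is.null(b$neph_visits)) b$neph_visits)
    vis <- unique(vis)
    neph_key <- if (is.null(b$neph_visits)) character(0) else
      paste(b$neph_visits$hospital, b$neph_visits$day)
    for (h in unique(vis$hospital)) {
      per_h[[h]]$persons[[length(per_h[[h]]$persons) + 1]] <-
        data.frame(person_id = pid_by_h[[h]], identity = b$identity,
                   birth_year = b$birth_year, sex = b$sex, stringsAsFactors = FALSE)
    }
    for (r in seq_len(nrow(vis))) {
      h <- vis$hospital[r]; d <- vis$day[r]
      vid <- sprintf("%s_v%05d_%04d", h, b$idx, d)
      dept <- if (paste(h, d) %in% neph_key) "nephrology" else
        DEPARTMENTS[1 + (b$idx + d) %% length(DEPARTMENTS)]
      per_h[[h]]$visits[[length(per_h[[h]]$visits) + 1]] <-
        data.frame(visit_id = vid, person_id = pid_by_h[[h]],
                   visit_date = format(ws + d), department = dept,
                   stringsAsFactors = FALSE)
    }
    e <- b$events
    if (nrow(e) > 0) {
      e$visit_id <- sprintf("%s_v%05d_%04d", e$hospital, b$idx, e$day)
      e$event_id <- sprintf("%s_e%05d_%03d", e$hospital, b$idx, seq_len(nrow(e)))
      for (h in unique(e$hospital)) {
        eh <- e[e$hospital == h, , drop = FALSE]
        per_h[[h]]$events[[length(per_h[[h]]$events) + 1]] <-
          data.frame(event_id = eh$event_id, visit_id = eh$visit_id, kind = eh$kind,
                     concept_id = eh$concept, value = eh$value, unit = eh$unit,
                     event_date = format(ws + eh$day), stringsAsFactors = FALSE)
      }
    }
    sat <- b$per_hospital_day
    truth_rows[[b$idx]] <- data.frame(
      identity = b$identity, phenotype = b$phenotype,
      hospitals = paste(sort(b$hospitals), collapse = "|"),
      onset_date = if (is.na(b$onset_day)) NA_character_ else format(ws + b$onset_day),
      transfer_date = if (is.na(b$transfer_day)) NA_character_ else format(ws + b$transfer_day),
      diagnosis_date = if (is.na(b$diagnosis_day)) NA_character_ else format(ws + b$diagnosis_day),
      per_hospital_satisfiable = as.character(jsonlite::toJSON(
        lapply(as.list(sat), function(d) if (is.na(d)) NULL else format(ws + d)),
        auto_unbox = TRUE, null = "null")),
      stringsAsFactors = FALSE)
  }

  stores <- lapply(hosp_ids, function(h) {
    p <- do.call(rbind, per_h[[h]]$persons)
    v <- do.call(rbind, per_h[[h]]$visits)
    e <- do.call(rbind, per_h[[h]]$events) %||% empty_events()
    if (is.null(e)) e <- empty_events()
    e$value <- as.numeric(e$value)
    ehr_store(h, order_by(p, "person_id"), order_by(v, "visit_id"),
              order_by(e, "event_id"))
  })
  names(stores) <- hosp_ids
  truth <- reset_rownames(do.call(rbind, truth_rows))
  for (col in c("onset_date", "transfer_date", "diagnosis_date"))
    truth[[col]] <- as.Date(truth[[col]])
  structure(list(stores = stores, truth = truth, config = config),
            class = "consortium")
}

# re-verify every emitted patient against the brute-force oracle
verify_consortium <- function(cons) {
  kt <- kidney_events_by_identity(cons$stores)
  for (i in seq_len(nrow(cons$truth))) {
    tr <- cons$truth[i, ]
    k <- kt[[tr$identity]]
    union_v <- if (is.null(k)) list(met = FALSE) else
      ckd_brute_oracle(k$day, k$abnormal)
    hosp <- strsplit(tr$hospitals, "|", fixed = TRUE)[[1]]
    per_h_met <- vapply(hosp, function(h) {
      kh <- k[k$hospital == h, , drop = FALSE]
      ckd_brute_oracle(kh$day, kh$abnormal)$met
    }, logical(1))
    bad <- switch(tr$phenotype,
      multicenter_ckd = !union_v$met || any(per_h_met),
      transferred_ckd = !union_v$met || sum(per_h_met) != 1,
      recovery_confounder = union_v$met,
      control = union_v$met,
      excluded = FALSE)
    abort_if(bad, "generator self-check failed for patient ", tr$identity,
             " (", tr$phenotype, ")")
    # fragmentation: no single hospital holds all visits
    n_vis <- vapply(cons$stores[hosp], function(s) {
      pid <- s$persons$person_id[s$persons$identity == tr$identity]
      sum(s$visits$person_id %in% pid)
    }, numeric(1))
    abort_if(sum(n_vis > 0) < 2, "fragmentation violated for patient ", tr$identity)
  }
  invisible(cons)
}

# per-identity kidney measurement table: hospital, day, abnormal
kidney_events_by_identity <- function(stores) {
  rows <- lapply(stores, function(s) {
    m <- s$events[s$events$kind == "measurement" &
                    s$events$concept_id %in% c("meas_egfr", "meas_acr", "meas_scr"), ,
                  drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    vis <- s$visits
    pid <- vis$person_id[match(m$visit_id, vis$visit_id)]
    idn <- s$persons$identity[match(pid, s$persons$person_id)]
    abn <- (m$concept_id == "meas_egfr" & m$value < 60) |
      (m$concept_id == "meas_acr" & m$value > 30) |
      (m$concept_id == "meas_scr" & m$value > 115)
    # only eGFR results in normal range count as recovery markers
    keep <- abn | m$concept_id == "meas_egfr"
    data.frame(identity = idn[keep], hospital = s$hospital_id,
               day = as.integer(m$event_date[keep]), abnormal = abn[keep],
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  split(all, all$identity)
}

#' Add exclusion decoys to a consortium
#'
#' Appends patients carrying a nephrology visit or a kidney-disease diagnosis
#' (and a CKD-like measurement pattern, so that failing to exclude them would
#' show up as false positives). Decoys are labeled `excluded` in the ground
#' truth. With `fraction = 0` the consortium is returned unchanged.
#'
#' @param cons a `consortium`.
#' @param fraction decoys to add, as a fraction of the cohort size.
#' @return the extended `consortium`.
#' @export
exclusion_noise <- function(cons, fraction) {
  if (fraction == 0) return(cons)
  cfg <- cons$config
  cfg$decoy_fraction <- cfg$decoy_fraction + fraction
  generate_consortium(cfg)
}

#' Write a consortium to disk
#'
#' Per-hospital OMOP-lite CSV directories plus ground truth as JSON lines
#' (one patient per line).
#'
#' @param cons a `consortium`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_consortium <- function(cons, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (h in names(cons$stores)) write_store(cons$stores[[h]], file.path(dir, h))
  lines <- vapply(seq_len(nrow(cons$truth)), function(i) {
    r <- as.list(cons$truth[i, ])
    r$onset_date <- if (is.na(r$onset_date)) NULL else format(r$onset_date)
    r$transfer_date <- if (is.na(r$transfer_date)) NULL else format(r$transfer_date)
    r$diagnosis_date <- if (is.na(r$diagnosis_date)) NULL else format(r$diagnosis_date)
    r$per_hospital_satisfiable <- jsonlite::fromJSON(r$per_hospital_satisfiable,
                                                     simplifyVector = FALSE)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, file.path(dir, "ground_truth.jsonl"))
  invisible(dir)
}
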