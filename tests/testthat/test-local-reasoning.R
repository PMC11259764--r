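rules <- default_ckd_ruleset()
vocab <- default_ckd_vocabulary()
map <- build_hypernym_map(vocab, 0.7)

test_that("initiation protocol screens on tests, departments and diagnoses", {
  s <- tiny_store()
  # p1: eGFR tests, cardiology/emergency visits only -> eligible
  expect_true(initiation_protocol(s, "p1", rules)$eligible)

  # nephrology visit excludes
  s2 <- tiny_store()
  s2$visits$department[s2$visits$visit_id == "v2"] <- "nephrology"
  r <- initiation_protocol(s2, "p1", rules)
  expect_false(r$eligible)
  expect_equal(r$reasons, "NEPHROLOGY_VISIT")

  # kidney-disease diagnosis excludes
  s3 <- tiny_store()
  s3$events$concept_id[s3$events$event_id == "e2"] <- "dx_ckd"
  r3 <- initiation_protocol(s3, "p1", rules)
  expect_false(r3$eligible)
  expect_equal(r3$reasons, "KIDNEY_DIAGNOSIS")

  # p2 has a potassium test but no kidney-function test -> ineligible
  r2 <- initiation_protocol(tiny_store(), "p2", rules)
  expect_false(r2$eligible)
  expect_equal(r2$reasons, "NO_KIDNEY_TEST")
})

test_that("measurement rules fire on strict comparison", {
  mk <- function(value) {
    s <- tiny_store()
    s$events$value[s$events$event_id == "e1"] <- value
    derive_visit_findings(s, "v1", rules)
  }
  f55 <- mk(55)
  expect_true(any(f55$concept_id == "lf_decreased_egfr" & f55$positive))
  # boundary: eGFR exactly 60 is not decreased ("lower than 60"), but emits
  # the normal-observation recovery marker
  f60 <- mk(60)
  row <- f60[f60$concept_id == "lf_decreased_egfr", ]
  expect_equal(nrow(row), 1)
  expect_false(row$positive)
})

test_that("potassium evidence from three provenances converges on one hypernym", {
  persons <- data.frame(person_id = "p1", identity = "330182199001011234",
                        birth_year = 1950L, sex = "female", stringsAsFactors = FALSE)
  visits <- data.frame(visit_id = "v1", person_id = "p1", visit_date = "2019-04-04",
                       department = "cardiology", stringsAsFactors = FALSE)
  events <- data.frame(
    event_id = c("e1", "e2", "e3"), visit_id = "v1",
    kind = c("diagnosis", "measurement", "drug"),
    concept_id = c("dx_hyperkalemia", "meas_k", "rx_k_binder"),
    value = c(NA, 5.8, NA), unit = c(NA, "mmol/L", NA),
    event_date = "2019-04-04", stringsAsFactors = FALSE)
  s <- ehr_store("H", persons, visits, events)
  f <- derive_visit_findings(s, "v1", rules)
  expect_equal(nrow(f), 3)
  expect_setequal(f$provenance, c("diagnosis", "measurement", "drug"))
  hyp <- unname(map$entries[f$concept_id])
  expect_equal(unique(hyp), "hyp_abnormal_blood_potassium")

  # same-day findings collapse to ONE intermediate finding
  dig <- hash_identity(normalize_identity(persons$identity), consortium_salt)$digest
  inter <- abstract_findings(f, map, setNames(dig, "p1"))
  expect_equal(nrow(inter), 1)
  expect_equal(inter$hypernym_concept_id, "hyp_abnormal_blood_potassium")
  expect_true(inter$positive)
  # privacy contract: no value/provenance/identity fields survive abstraction
  expect_setequal(names(inter), c("digest", "date", "hypernym_concept_id", "positive"))
})

test_that("abstraction drops unmapped leaves with a warning, empty in empty out", {
  f <- derive_findings(tiny_store(), rules)
  dig <- setNames(rep(strrep("a", 64), 2), c("p1", "p2"))
  bad_map <- structure(list(entries = character(0), similarity_threshold = 0.7,
                            low_cohesion = character(0), unmapped = character(0)),
                       class = "hypernym_map")
  expect_warning(out <- abstract_findings(f, bad_map, dig), "unmapped")
  expect_equal(nrow(out), 0)
  expect_equal(nrow(abstract_findings(f[0, ], map, dig)), 0)
})

test_that("findings are per-visit local (permutation of other visits)", {
  s <- tiny_store()
  base <- derive_visit_findings(s, "v1", rules)
  s2 <- tiny_store()
  s2$visits <- s2$visits[rev(seq_len(nrow(s2$visits))), ]
  s2$events <- s2$events[sample(nrow(s2$events)), ]
  expect_equal(derive_visit_findings(s2, "v1", rules), base)
  # store-level derivation agrees with per-visit calls
  all_f <- derive_findings(s, rules)
  per_visit <- do.call(rbind, lapply(s$visits$visit_id, function(v)
    derive_visit_findings(s, v, rules)))
  ord <- function(df) {
    df <- df[order(df$person_id, df$date, df$concept_id, df$source_event_id), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(all_f), ord(per_visit))
})

test_that("chronicity detection matches its stated examples", {
  tl <- function(dates, pos) data.frame(date = as.Date(dates), positive = pos)
  # two abnormals 2019-04-04 / 2020-08-02, nothing between -> met on the second
  v <- detect_ckd_criteria(tl(c("2019-04-04", "2020-08-02"), c(TRUE, TRUE)))
  expect_true(v$met)
  expect_equal(v$first_met_date, as.Date("2020-08-02"))
  expect_equal(v$pair, as.Date(c("2019-04-04", "2020-08-02")))

  # recovery reset: abnormal d0, normal d60, abnormal d150 -> not met
  d0 <- as.Date("2019-01-01")
  v2 <- detect_ckd_criteria(data.frame(date = d0 + c(0, 60, 150),
                                       positive = c(TRUE, FALSE, TRUE)))
  expect_false(v2$met)

  # window boundary is inclusive at 90 days
  expect_false(detect_ckd_criteria(data.frame(date = d0 + c(0, 89),
                                              positive = TRUE))$met)
  v90 <- detect_ckd_criteria(data.frame(date = d0 + c(0, 90), positive = TRUE))
  expect_true(v90$met)
  expect_equal(as.integer(v90$pair[2] - v90$pair[1]), 90)
})

test_that("chronicity detection agrees with the brute-force oracle", {
  set.seed(1234)
  for (rep in 1:500) {
    tl <- random_timeline(sample(1:12, 1))
    got <- detect_ckd_criteria(tl)
    want <- brute_ckd(tl)
    expect_identical(got$met, want$met)
    if (want$met) expect_identical(got$first_met_date, want$first_met_date)
  }
  # targeted boundary sweeps at exactly 89/90 days with surrounding normals
  d0 <- as.Date("2020-01-01")
  for (gap in c(89, 90)) for (nrm_at in c(NA, 45, 91)) {
    dates <- d0 + c(0, gap); pos <- c(TRUE, TRUE)
    if (!is.na(nrm_at)) { dates <- c(dates, d0 + nrm_at); pos <- c(pos, FALSE) }
    tl <- data.frame(date = dates, positive = pos)
    expect_identical(detect_ckd_criteria(tl)$met, brute_ckd(tl)$met)
  }
})

test_that("adding an abnormal finding never un-meets the criteria", {
  set.seed(55)
  for (rep in 1:100) {
    tl <- random_timeline(sample(2:10, 1))
    before <- detect_ckd_criteria(tl)$met
    tl2 <- rbind(tl, data.frame(date = as.Date("2018-01-01") + sample.int(900, 1),
                                positive = TRUE))
    after <- detect_ckd_criteria(tl2)$met
    if (before) expect_true(after)
  }
})

test_that("rule set round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ruleset(rules, path)
  r2 <- read_ruleset(path)
  expect_equal(r2$measurement_rules, rules$measurement_rules)
  expect_equal(r2$diagnosis_rules, rules$diagnosis_rules)
  expect_equal(r2$drug_rules, rules$drug_rules)
  expect_equal(r2$kidney_finding_concepts, rules$kidney_finding_concepts)
  expect_equal(r2$window_days, rules$window_days)
})
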