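# Shared fixtures (built in code) and independent oracles.

# --- tiny 3-level vocabulary: root <- hypernym <- leaves ---------------------
tiny_vocab <- function(embeddings = list(lf_a = c(1, 0), lf_b = c(1, 0))) {
  concept_graph(data.frame(
    concept_id = c("root", "hyp_k", "lf_a", "lf_b"),
    name = c("clinical finding", "abnormal kidney function",
             "eGFR G3b stage", "elevated ACR"),
    domain = c("observation", "observation", "observation", "observation"),
    parent_ids = c("", "root", "hyp_k", "hyp_k"),
    is_hypernym = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE), embeddings = embeddings)
}

# --- small hand-built store: 2 persons, 3 visits, 5 events -------------------
tiny_store <- function(hospital_id = "HA") {
  persons <- data.frame(
    person_id = c("p1", "p2"),
    identity = c("330182199001011234", "330182198505054321"),
    birth_year = c(1950L, 1962L), sex = c("female", "male"),
    stringsAsFactors = FALSE)
  visits <- data.frame(
    visit_id = c("v1", "v2", "v3"),
    person_id = c("p1", "p1", "p2"),
    visit_date = c("2019-04-04", "2019-05-10", "2019-06-01"),
    department = c("cardiology", "emergency", "endocrinology"),
    stringsAsFactors = FALSE)
  events <- data.frame(
    event_id = c("e1", "e2", "e3", "e4", "e5"),
    visit_id = c("v1", "v1", "v2", "v3", "v3"),
    kind = c("measurement", "diagnosis", "measurement", "measurement", "drug"),
    concept_id = c("meas_egfr", "dx_htn", "meas_egfr", "meas_k", "rx_k_binder"),
    value = c(55.3, NA, 48.2, 5.8, NA),
    unit = c("mL/min", NA, "mL/min", "mmol/L", NA),
    event_date = c("2019-04-04", "2019-04-04", "2019-05-10", "2019-06-01", "2019-06-01"),
    stringsAsFactors = FALSE)
  ehr_store(hospital_id, persons, visits, events)
}

# --- independent brute-force chronicity oracle -------------------------------
# O(n^2) over all abnormal pairs with an intervening-normal scan; written
# against the rule statement, independent of detect_ckd_criteria's algorithm.
brute_ckd <- function(timeline, window_days = 90) {
  ab <- sort(unique(as.Date(timeline$date[timeline$positive])))
  nm <- sort(unique(as.Date(timeline$date[!timeline$positive])))
  first <- as.Date(NA)
  for (i in seq_along(ab)) for (j in seq_along(ab)) {
    if (as.integer(ab[j] - ab[i]) >= window_days &&
        !any(nm > ab[i] & nm < ab[j])) {
      if (is.na(first) || ab[j] < first) first <- ab[j]
    }
  }
  list(met = !is.na(first), first_met_date = first)
}

# random finding timeline generator for property tests
random_timeline <- function(n, origin = as.Date("2018-01-01"), span = 900) {
  data.frame(date = origin + sample.int(span, n, replace = TRUE),
             positive = stats::runif(n) < 0.7)
}

# brute-force hypernym assignment: enumerate all hypernym ancestors, filter by
# threshold on leaf_similarity, pick max depth (lexicographic tie-break),
# else most general
brute_hypernym_map <- function(graph, threshold) {
  hyps <- graph$concepts$concept_id[graph$concepts$is_hypernym]
  out <- character(0)
  for (leaf in sort(graph$leaves)) {
    cand <- intersect(concept_ancestors(graph, leaf, include_self = TRUE), hyps)
    if (length(cand) == 0) next
    sims <- vapply(cand, function(h) leaf_similarity(graph, h), numeric(1))
    pass <- cand[sims >= threshold]
    pick <- if (length(pass) > 0) {
      d <- graph$depth[pass]; sort(pass[d == max(d)])[[1]]
    } else {
      d <- graph$depth[cand]; sort(cand[d == min(d)])[[1]]
    }
    out[[leaf]] <- pick
  }
  out
}

consortium_salt <- "test-consortium-salt"
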