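# The collaborative reasoning protocol: initiation, alignment, ROI
# designation, ROI-restricted local reasoning, and summarization. One sponsor
# per process; every message (eligibility announcement, online subgraph, ROI
# designation) is appended to the shared hash-chained ledger, so a full run is
# traceable and a pure function of (stores, vocabulary, rules, salt, series).

kidney_hypernyms <- function(rules, map)
  unique(stats::na.omit(unname(map$entries[rules$kidney_finding_concepts])))

hypernym_whitelist <- function(graph)
  graph$concepts$concept_id[graph$concepts$is_hypernym]

# pooled data.frame view over a list of subgraphs
pool_subgraphs <- function(subgraphs) {
  empty_f <- data.frame(digest = character(0), date = as.Date(character(0)),
                        concept_id = character(0), positive = logical(0),
                        origin = character(0), stringsAsFactors = FALSE)
  empty_v <- data.frame(digest = character(0), date = as.Date(character(0)),
                        origin = character(0), stringsAsFactors = FALSE)
  f <- do.call(rbind, lapply(subgraphs, function(g)
    if (nrow(g$findings) == 0) NULL else
      data.frame(digest = g$patient_digest, date = g$findings$date,
                 concept_id = g$findings$concept_id, positive = g$findings$positive,
                 origin = g$origin, stringsAsFactors = FALSE)))
  v <- do.call(rbind, lapply(subgraphs, function(g)
    if (length(g$visits) == 0) NULL else
      data.frame(digest = g$patient_digest, date = g$visits, origin = g$origin,
                 stringsAsFactors = FALSE)))
  fix <- function(df, empty) {
    if (is.null(df)) return(empty)
    df$date <- as.Date(df$date)
    unique(df)
  }
  list(findings = fix(f, empty_f), visits = fix(v, empty_v))
}

#' Initiation round: eligibility screening and initial kidney findings
#'
#' Every node screens its patients with the initiation protocol, packages the
#' eligible patients' kidney-function intermediate findings (abnormal and
#' normal-observation labels) together with their visit dates as online
#' subgraphs, and prepares an eligibility announcement. Ineligible patients'
#' findings never leave their node; only digests plus exclusion reason codes
#' (nephrology visit / kidney diagnosis) are announced so the sponsor can
#' apply consortium-wide exclusion.
#'
#' @param stores named list of `ehr_store` (one per node).
#' @param rules a `rule_set`.
#' @param map a `hypernym_map`.
#' @param vocab the `concept_graph` (source of the hypernym whitelist).
#' @param salt consortium salt.
#' @param salt_id salt label.
#' @param series process series number.
#' @return list with `announcements` (per node), `subgraphs` (list of
#'   `online_subgraph`), `eligibility` (data.frame `hospital_id`, `digest`,
#'   `eligible`, `reasons`).
#' @export
run_initiation_round <- function(stores, rules, map, vocab, salt,
                                 salt_id = "consortium", series = 1L) {
  abort_if(is.null(rules), "node without rules: protocol abort")
  allowed <- hypernym_whitelist(vocab)
  ann <- list(); sgs <- list(); elig_rows <- list()
  for (h in names(stores)) {
    s <- stores[[h]]
    digests <- store_digests(s, salt, salt_id)
    findings <- derive_findings(s, rules)
    kid <- findings[findings$concept_id %in% rules$kidney_finding_concepts, , drop = FALSE]
    inter <- abstract_findings(kid, map, digests)

    ev <- s$events
    vper <- stats::setNames(s$visits$person_id, s$visits$visit_id)
    has_test <- unique(vper[ev$visit_id[ev$kind == "measurement" &
                                          ev$concept_id %in% rules$kidney_analyte_concepts]])
    has_neph <- unique(s$visits$person_id[tolower(s$visits$department) %in%
                                            tolower(rules$nephrology_departments)])
    has_kdx <- unique(vper[ev$visit_id[ev$kind == "diagnosis" &
                                         ev$concept_id %in% rules$kidney_disease_dx_concepts]])
    pid <- s$persons$person_id
    eligible <- pid %in% has_test & !pid %in% has_neph & !pid %in% has_kdx
    reasons <- vapply(pid, function(p) paste(c(
      if (!p %in% has_test) "NO_KIDNEY_TEST",
      if (p %in% has_neph) "NEPHROLOGY_VISIT",
      if (p %in% has_kdx) "KIDNEY_DIAGNOSIS"), collapse = "|"), character(1))
    elig_rows[[h]] <- data.frame(hospital_id = h, digest = unname(digests[pid]),
                                 eligible = eligible, reasons = unname(reasons),
                                 stringsAsFactors = FALSE)

    hard <- grepl("NEPHROLOGY_VISIT|KIDNEY_DIAGNOSIS", reasons)
    ann[[h]] <- list(type = "eligibility", origin = h, series = as.integer(series),
                     eligible = as.list(sort(unname(digests[pid[eligible]]))),
                     excluded = lapply(sort(unname(digests[pid[hard]])), function(d) {
                       p <- pid[digests[pid] == d][[1]]
                       list(digest = d,
                            reasons = as.list(strsplit(reasons[[match(p, pid)]], "|",
                                                       fixed = TRUE)[[1]]))
                     }))

    # Subgraphs go out for locally eligible patients and for patients whose
    # only local failure is the absence of a kidney test: under fragmentation
    # such a node still holds the visit pathway (dates only) the sponsor
    # needs for transfer reasoning. Hard-excluded patients send nothing.
    send <- eligible | reasons == "NO_KIDNEY_TEST"
    for (p in sort(pid[send])) {
      d <- digests[[p]]
      fi <- inter[inter$digest == d, c("date", "hypernym_concept_id", "positive"),
                  drop = FALSE]
      vd <- s$visits$visit_date[s$visits$person_id == p]
      sgs[[length(sgs) + 1]] <- build_online_subgraph(d, fi, vd, origin = h,
                                                      series = series,
                                                      allowed_concepts = allowed,
                                                      salt_id = salt_id)
    }
  }
  list(announcements = ann, subgraphs = sgs,
       eligibility = reset_rownames(do.call(rbind, elig_rows)))
}

#' Designate regions of interest from merged initial findings
#'
#' For every non-excluded patient whose merged (all-hospital) kidney-function
#' timeline contains a qualifying chronicity pair, the ROI spans from the
#' first to the last abnormal kidney finding in the merged series; patients
#' without a qualifying pair get no ROI.
#'
#' @param subgraphs initiation-round subgraphs from all nodes.
#' @param rules a `rule_set`.
#' @param map a `hypernym_map`.
#' @param excluded digests excluded consortium-wide.
#' @return data.frame `digest`, `start`, `end` (Dates), sorted by digest.
#' @export
designate_roi <- function(subgraphs, rules, map, excluded = character(0)) {
  khyp <- kidney_hypernyms(rules, map)
  pooled <- pool_subgraphs(subgraphs)
  f <- pooled$findings
  f <- f[f$concept_id %in% khyp & !f$digest %in% excluded, , drop = FALSE]
  out <- list()
  for (d in sort(unique(f$digest))) {
    tl <- f[f$digest == d, c("date", "positive"), drop = FALSE]
    v <- detect_ckd_criteria(tl, rules$window_days)
    if (v$met) {
      ab <- tl$date[tl$positive]
      out[[length(out) + 1]] <- data.frame(digest = d, start = min(ab), end = max(ab),
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(digest = character(0), start = as.Date(character(0)),
                      end = as.Date(character(0)), stringsAsFactors = FALSE))
  reset_rownames(do.call(rbind, out))
}

#' ROI-restricted local reasoning round
#'
#' Each node derives per-visit findings for its ROI patients strictly within
#' the ROI window (events outside every ROI are never processed for export),
#' abstracts them to hypernyms, and packages subgraphs.
#'
#' @inheritParams run_initiation_round
#' @param rois data.frame from [designate_roi()].
#' @return list of `online_subgraph`.
#' @export
local_reasoning_round <- function(stores, rois, rules, map, vocab, salt,
                                  salt_id = "consortium", series = 1L) {
  allowed <- hypernym_whitelist(vocab)
  sgs <- list()
  for (h in names(stores)) {
    s <- stores[[h]]
    digests <- store_digests(s, salt, salt_id)
    rev_dig <- stats::setNames(names(digests), unname(digests))
    findings <- derive_findings(s, rules)
    fdig <- unname(digests[findings$person_id])
    for (i in seq_len(nrow(rois))) {
      d <- rois$digest[[i]]
      p <- unname(rev_dig[d])
      if (length(p) == 0) p <- NA_character_
      if (is.na(p)) next
      sel <- fdig == d & findings$date >= rois$start[[i]] & findings$date <= rois$end[[i]]
      fi <- findings[sel, , drop = FALSE]
      inter <- abstract_findings(fi, map, digests)
      vd <- s$visits$visit_date[s$visits$person_id == p]
      vd <- vd[vd >= rois$start[[i]] & vd <= rois$end[[i]]]
      sgs[[length(sgs) + 1]] <- build_online_subgraph(
        d, inter[c("date", "hypernym_concept_id", "positive")], vd, origin = h,
        series = series, allowed_concepts = allowed, salt_id = salt_id)
    }
  }
  sgs
}

local_person <- function(rev_sponsor, d)
  if (d %in% names(rev_sponsor)) unname(rev_sponsor[[d]]) else NA_character_

new_cds_result <- function(digest, local_person_id, ckd_met, first_met_date, pair,
                           group, roi, risks, evidence, series) {
  structure(list(digest = digest, local_person_id = local_person_id,
                 ckd_met = ckd_met, first_met_date = first_met_date, pair = pair,
                 group = group, roi = roi, risks = risks, evidence = evidence,
                 series = series), class = "cds_result")
}

#' @export
print.cds_result <- function(x, ...) {
  cat(sprintf("<cds_result %s> ckd_met=%s group=%s first_met=%s risks=%d\n",
              substr(x$digest, 1, 8), x$ckd_met, x$group,
              format(x$first_met_date), nrow(x$risks)))
  invisible(x)
}

#' Summarization reasoning over merged multicenter findings
#'
#' The sponsor pools ROI-round findings per patient, re-derives the
#' chronicity verdict on the merged timeline, and classifies each met patient:
#' `transferred` when one hospital's findings alone satisfy the criteria and
#' the patient visited a different hospital after that date; `multicenter_data`
#' when no single hospital's findings suffice but the merged set does;
#' `single_center` otherwise. Eligible patients without a qualifying merged
#' pair are reported with `ckd_met = FALSE` and group `none`. Risks are the
#' positive risk-catalog hypernyms found within the ROI, with dates and origin
#' tags, and the evidence trail is the full merged finding series.
#'
#' @param init initiation-round output ([run_initiation_round()]).
#' @param roi_subgraphs ROI-round subgraphs ([local_reasoning_round()]).
#' @param rois ROI table ([designate_roi()]).
#' @param rules a `rule_set`.
#' @param map a `hypernym_map`.
#' @param sponsor_store the sponsoring hospital's `ehr_store` (for local
#'   person references on results).
#' @param salt,salt_id consortium salt and label.
#' @param series process series number.
#' @param excluded digests excluded consortium-wide.
#' @return named list (by digest) of `cds_result`, sorted by digest.
#' @export
summarize_cohort <- function(init, roi_subgraphs, rois, rules, map, sponsor_store,
                             salt, salt_id = "consortium", series = 1L,
                             excluded = character(0)) {
  khyp <- kidney_hypernyms(rules, map)
  sponsor_digests <- store_digests(sponsor_store, salt, salt_id)
  rev_sponsor <- stats::setNames(names(sponsor_digests), unname(sponsor_digests))
  pooled_roi <- pool_subgraphs(roi_subgraphs)
  pooled_init <- pool_subgraphs(init$subgraphs)

  elig <- init$eligibility
  cohort <- sort(setdiff(unique(elig$digest[elig$eligible]), excluded))
  results <- list()
  for (d in cohort) {
    f <- pooled_roi$findings[pooled_roi$findings$digest == d, , drop = FALSE]
    roi_row <- rois[rois$digest == d, , drop = FALSE]
    if (nrow(roi_row) == 0) {
      fk <- pooled_init$findings
      fk <- fk[fk$digest == d & fk$concept_id %in% khyp, , drop = FALSE]
      results[[d]] <- new_cds_result(
        d, local_person(rev_sponsor, d), ckd_met = FALSE,
        first_met_date = as.Date(NA), pair = NULL, group = "none", roi = NULL,
        risks = data.frame(concept_id = character(0), date = as.Date(character(0)),
                           origin = character(0), stringsAsFactors = FALSE),
        evidence = reset_rownames(order_by(
          fk[c("date", "concept_id", "positive", "origin")],
          c("date", "concept_id", "origin"))),
        series = as.integer(series))
      next
    }
    kid <- f[f$concept_id %in% khyp, , drop = FALSE]
    verdict <- detect_ckd_criteria(kid[c("date", "positive")], rules$window_days)
    origins <- sort(unique(kid$origin))
    per_origin <- lapply(origins, function(o)
      detect_ckd_criteria(kid[kid$origin == o, c("date", "positive")], rules$window_days))
    names(per_origin) <- origins
    met_alone <- origins[vapply(per_origin, `[[`, logical(1), "met")]

    group <- "none"
    if (verdict$met) {
      if (length(met_alone) == 0) {
        group <- "multicenter_data"
      } else {
        dates_alone <- as.Date(vapply(met_alone, function(o)
          format(per_origin[[o]]$first_met_date), character(1)))
        o_star <- met_alone[[which.min(dates_alone)]]
        d_star <- min(dates_alone)
        vis <- pooled_init$visits[pooled_init$visits$digest == d, , drop = FALSE]
        transferred <- any(vis$origin != o_star & vis$date > d_star)
        group <- if (transferred) "transferred" else "single_center"
      }
    }
    risk <- f[f$positive & f$concept_id %in% rules$risk_hypernyms &
                f$date >= roi_row$start & f$date <= roi_row$end, , drop = FALSE]
    results[[d]] <- new_cds_result(
      d, local_person(rev_sponsor, d), ckd_met = verdict$met,
      first_met_date = verdict$first_met_date, pair = verdict$pair, group = group,
      roi = list(start = roi_row$start, end = roi_row$end),
      risks = reset_rownames(order_by(risk[c("concept_id", "date", "origin")],
                                      c("date", "concept_id", "origin"))),
      evidence = reset_rownames(order_by(f[c("date", "concept_id", "positive", "origin")],
                                         c("date", "concept_id", "origin"))),
      series = as.integer(series))
  }
  results[order(names(results))]
}

#' Run the full collaborative reasoning process
#'
#' Executes the five steps end to end over in-memory stores: (1) per-node
#' initiation screening with ledger-broadcast announcements and initial
#' kidney-finding subgraphs, (2) digest-based patient alignment at the
#' sponsor, (3) ROI designation and broadcast, (4) ROI-restricted local
#' reasoning at every node, (5) summarization into per-patient CDS results.
#' Every exchanged message passes through the hash-chained ledger; the sponsor
#' consumes subgraphs by deserializing ledger payloads (with privacy
#' re-validation), not by peeking at other nodes' memory.
#'
#' @param stores named list of `ehr_store`.
#' @param sponsor hospital id of the sponsoring node (must name an element of
#'   `stores`).
#' @param vocab a `concept_graph` (default: the CKD vocabulary).
#' @param rules a `rule_set` (default: the CKD rule set).
#' @param map a `hypernym_map` (default: built from `vocab` at threshold 0.7).
#' @param salt consortium salt.
#' @param salt_id salt label.
#' @param series process series number.
#' @return object of class `collab_run`: list with `results` (named list of
#'   `cds_result`), `ledger`, `alignment`, `eligibility`, `rois`,
#'   `excluded`, `delivery_log`, `sponsor`, `series`.
#' @export
run_collaboration <- function(stores, sponsor, vocab = default_ckd_vocabulary(),
                              rules = default_ckd_ruleset(),
                              map = build_hypernym_map(vocab), salt,
                              salt_id = "consortium", series = 1L) {
  abort_if(!sponsor %in% names(stores), "sponsor must be one of the nodes")
  allowed <- hypernym_whitelist(vocab)
  chain <- ledger_new()

  # step 1: initiation at every node; announcements + subgraphs to the ledger
  init <- run_initiation_round(stores, rules, map, vocab, salt, salt_id, series)
  for (h in names(stores))
    chain <- ledger_append(chain, as.character(
      jsonlite::toJSON(init$announcements[[h]], auto_unbox = TRUE, digits = NA)))
  for (g in init$subgraphs) chain <- ledger_append(chain, serialize_subgraph(g))
  n_init_blocks <- length(chain$blocks)

  # sponsor side: read round-1 payloads back off the ledger
  payloads <- ledger_payloads(chain)
  parsed <- lapply(payloads, jsonlite::fromJSON, simplifyVector = FALSE)
  is_ctrl <- vapply(parsed, function(p) !is.null(p$type), logical(1))
  r1_subgraphs <- lapply(payloads[!is_ctrl], deserialize_subgraph,
                         allowed_concepts = allowed)
  excluded <- sort(unique(unlist(lapply(parsed[is_ctrl], function(p)
    vapply(p$excluded, `[[`, "", "digest")))))

  # step 2: alignment at the sponsor
  alignment <- align_patients(stores[[sponsor]],
                              Filter(function(g) g$origin != sponsor, r1_subgraphs),
                              salt, salt_id)

  # step 3: ROI designation, broadcast
  rois <- designate_roi(r1_subgraphs, rules, map, excluded = excluded)
  roi_msg <- list(type = "roi", origin = sponsor, series = as.integer(series),
                  rois = lapply(seq_len(nrow(rois)), function(i)
                    list(digest = rois$digest[[i]], start = format(rois$start[[i]]),
                         end = format(rois$end[[i]]))))
  chain <- ledger_append(chain, as.character(
    jsonlite::toJSON(roi_msg, auto_unbox = TRUE, digits = NA)))

  # step 4: ROI-restricted reasoning at every node
  r4 <- local_reasoning_round(stores, rois, rules, map, vocab, salt, salt_id, series)
  for (g in r4) chain <- ledger_append(chain, serialize_subgraph(g))
  r4_subgraphs <- lapply(ledger_payloads(chain)[-seq_len(n_init_blocks + 1L)],
                         deserialize_subgraph, allowed_concepts = allowed)

  # step 5: summarization at the sponsor
  init_sponsor <- list(subgraphs = r1_subgraphs, eligibility = init$eligibility)
  results <- summarize_cohort(init_sponsor, r4_subgraphs, rois, rules, map,
                              stores[[sponsor]], salt, salt_id, series,
                              excluded = excluded)
  log <- broadcast(chain, names(stores), series = series)

  structure(list(results = results, ledger = chain, alignment = alignment,
                 eligibility = init$eligibility, rois = rois, excluded = excluded,
                 delivery_log = log, sponsor = sponsor, series = as.integer(series)),
            class = "collab_run")
}

#' @export
print.collab_run <- function(x, ...) {
  met <- sum(vapply(x$results, `[[`, logical(1), "ckd_met"))
  cat(sprintf("<collab_run series %d, sponsor %s> %d patients reasoned, %d met criteria, %d ledger blocks\n",
              x$series, x$sponsor, length(x$results), met, length(x$ledger$blocks)))
  invisible(x)
}

#' Export a CDS result as a visualization timeline document
#'
#' Ordered events with origin markers (local to the sponsor vs remote), ROI
#' bounds, the supporting chronicity pair and the risk list, as canonical
#' JSON for a timeline front end.
#'
#' @param result a `cds_result`.
#' @param sponsor sponsoring hospital id (defines the local origin class).
#' @return length-1 character (JSON document).
#' @export
export_timeline <- function(result, sponsor) {
  ev <- result$evidence
  entries <- lapply(seq_len(nrow(ev)), function(i)
    list(concept_id = ev$concept_id[[i]], date = format(ev$date[[i]]),
         origin = ev$origin[[i]],
         origin_class = if (identical(ev$origin[[i]], sponsor)) "local" else "remote",
         positive = ev$positive[[i]]))
  doc <- list(ckd_met = result$ckd_met,
              evidence = entries,
              first_met_date = if (is.na(result$first_met_date)) NULL else
                format(result$first_met_date),
              group = result$group,
              patient_digest = result$digest,
              risks = lapply(seq_len(nrow(result$risks)), function(i)
                list(concept_id = result$risks$concept_id[[i]],
                     date = format(result$risks$date[[i]]),
                     origin = result$risks$origin[[i]])),
              roi = if (is.null(result$roi)) NULL else
                list(start = format(result$roi$start), end = format(result$roi$end)),
              series = result$series,
              supporting_pair = if (is.null(result$pair)) NULL else
                as.list(format(result$pair)))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Validate a timeline document against the export schema
#'
#' @param json character scalar from [export_timeline()].
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_timeline <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  need <- c("ckd_met", "evidence", "group", "patient_digest", "risks", "series")
  miss <- setdiff(need, names(doc))
  abort_if(length(miss) > 0, "timeline missing key(s): ", paste(miss, collapse = ", "))
  abort_if(!is.logical(doc$ckd_met), "ckd_met must be boolean")
  abort_if(!doc$group %in% c("multicenter_data", "transferred", "single_center", "none"),
           "invalid group label")
  for (e in doc$evidence) {
    ok <- setequal(names(e), c("concept_id", "date", "origin", "origin_class", "positive"))
    abort_if(!ok, "invalid evidence entry")
    abort_if(!e$origin_class %in% c("local", "remote"), "invalid origin class")
  }
  abort_if(isTRUE(doc$ckd_met) && is.null(doc$roi), "met result must carry an ROI")
  invisible(TRUE)
}

#' Write CDS results as canonical JSON
#'
#' One JSON array, patients sorted by digest; byte-identical across identical
#' runs.
#'
#' @param run a `collab_run` (or named list of `cds_result`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cds_results <- function(run, path) {
  results <- if (inherits(run, "collab_run")) run$results else run
  sponsor <- if (inherits(run, "collab_run")) run$sponsor else ""
  docs <- vapply(results[order(names(results))], export_timeline, character(1),
                 sponsor = sponsor)
  writeLines(c("[", paste0(docs, c(rep(",", max(0, length(docs) - 1)), "")), "]"), path)
  invisible(path)
}

# ---- secure two-party comparison interface ---------------------------------

#' Registry for privately held measurement values
#'
#' Nodes register values under opaque references; [secure_compare()] answers
#' ordering queries over references without disclosing the values. The
#' shipped implementation is a plaintext trusted-evaluator reference: the
#' interface is what a garbled-circuit backend would substitute for.
#'
#' @return an environment-backed registry.
#' @export
secure_registry <- function() new.env(parent = emptyenv())

#' @rdname secure_registry
#' @param registry a registry from [secure_registry()].
#' @param ref opaque value reference.
#' @param value numeric value held privately by a node.
#' @export
register_value <- function(registry, ref, value) {
  assign(ref, as.numeric(value), envir = registry)
  invisible(ref)
}

#' Compare two privately held values by reference
#'
#' @param registry a registry from [secure_registry()].
#' @param ref_a,ref_b references previously registered.
#' @return one of `"<"`, `"="`, `">"` — the ordering only, never the values.
#' @export
secure_compare <- function(registry, ref_a, ref_b) {
  for (r in c(ref_a, ref_b))
    abort_if(!exists(r, envir = registry, inherits = FALSE),
             "unknown value reference: ", r)
  a <- get(ref_a, envir = registry); b <- get(ref_b, envir = registry)
  if (a < b) "<" else if (a > b) ">" else "="
}
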