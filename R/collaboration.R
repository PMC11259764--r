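# Online subgraphs and the simulated synchronization layer.
#
# The online subgraph is the only structure that crosses hospital boundaries:
# a hashed patient identity, virtual visit nodes carrying dates only, and
# virtual finding nodes carrying a hypernym concept and a positive/negative
# label. The blockchain of the deployed system is simulated here as a
# single-sequencer hash chain with synchronous broadcast: ordered,
# tamper-evident, traceable delivery — the contract the reasoning protocol
# relies on — without networking or consensus machinery.

FORBIDDEN_SUBGRAPH_FIELDS <- c("value", "unit", "identity", "person_id",
                               "department", "provenance", "source_event_id",
                               "leaf_concept_id", "name")

#' Build an online subgraph for one patient
#'
#' Validates the privacy contract at construction: findings may carry nothing
#' but a date, a hypernym concept and a positive label, and every concept must
#' come from the supplied hypernym whitelist. A value-bearing finding or a
#' non-hypernym concept is a hard privacy violation, not a warning.
#'
#' @param patient_digest hashed identity (64-char hex).
#' @param findings data.frame with exactly `date`, `hypernym_concept_id`,
#'   `positive` (as produced by [abstract_findings()], minus the digest
#'   column).
#' @param visit_dates Date vector of the patient's visit dates at the origin
#'   hospital (dates only — no department, no events).
#' @param origin origin hospital id.
#' @param series collaborative-process series number.
#' @param allowed_concepts hypernym whitelist (character vector).
#' @param salt_id salt label carried for alignment sanity checks.
#' @return object of class `online_subgraph`.
#' @export
build_online_subgraph <- function(patient_digest, findings, visit_dates, origin,
                                  series, allowed_concepts, salt_id = "consortium") {
  abort_if(!grepl("^[0-9a-f]{64}$", patient_digest),
           "patient_digest must be a 64-char lowercase hex digest")
  bad_cols <- intersect(names(findings), FORBIDDEN_SUBGRAPH_FIELDS)
  abort_if(length(bad_cols) > 0,
           "privacy violation: forbidden field(s) in subgraph findings: ",
           paste(bad_cols, collapse = ", "))
  need <- c("date", "hypernym_concept_id", "positive")
  abort_if(!setequal(names(findings), need),
           "subgraph findings must have exactly columns: ", paste(need, collapse = ", "))
  bad_con <- setdiff(unique(findings$hypernym_concept_id), allowed_concepts)
  abort_if(length(bad_con) > 0,
           "privacy violation: non-hypernym concept in subgraph: ",
           paste(bad_con, collapse = ", "))
  f <- data.frame(concept_id = as.character(findings$hypernym_concept_id),
                  date = format(as.Date(findings$date)),
                  positive = as.logical(findings$positive),
                  stringsAsFactors = FALSE)
  f <- unique(reset_rownames(order_by(f, c("date", "concept_id", "positive"))))
  structure(list(patient_digest = patient_digest,
                 salt_id = salt_id,
                 origin = origin,
                 series = as.integer(series),
                 visits = sort(unique(format(as.Date(visit_dates)))),
                 findings = f),
            class = "online_subgraph")
}

#' @export
print.online_subgraph <- function(x, ...) {
  cat(sprintf("<online_subgraph %s from %s> %d virtual visits, %d findings (series %d)\n",
              substr(x$patient_digest, 1, 8), x$origin, length(x$visits),
              nrow(x$findings), x$series))
  invisible(x)
}

#' Serialize an online subgraph to canonical JSON
#'
#' Sorted keys, sorted node lists, no floats: two serializations of the same
#' graph are byte-identical, which makes ledger payloads diffable and
#' deterministic.
#'
#' @param g an `online_subgraph`.
#' @return length-1 character (UTF-8 JSON).
#' @export
serialize_subgraph <- function(g) {
  fl <- lapply(seq_len(nrow(g$findings)), function(i)
    list(concept_id = g$findings$concept_id[[i]], date = g$findings$date[[i]],
         positive = g$findings$positive[[i]]))
  doc <- list(findings = fl, origin = g$origin, patient_digest = g$patient_digest,
              salt_id = g$salt_id, series = g$series, visits = as.list(g$visits))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
}

#' Deserialize and re-validate an online subgraph
#'
#' The deserializer re-checks the privacy invariants: only the canonical keys
#' may be present, findings may carry only concept/date/label, and (when a
#' whitelist is given) all concepts must be hypernyms. A payload smuggling a
#' `value` or identity field is rejected outright.
#'
#' @param json character scalar from [serialize_subgraph()].
#' @param allowed_concepts optional hypernym whitelist to enforce.
#' @return an `online_subgraph`.
#' @export
deserialize_subgraph <- function(json, allowed_concepts = NULL) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  need <- c("findings", "origin", "patient_digest", "salt_id", "series", "visits")
  extra <- setdiff(names(doc), need)
  abort_if(length(extra) > 0, "rejected subgraph payload: forbidden key(s): ",
           paste(extra, collapse = ", "))
  abort_if(!all(need %in% names(doc)), "subgraph payload missing required keys")
  fkeys <- c("concept_id", "date", "positive")
  for (f in doc$findings) {
    abort_if(!setequal(names(f), fkeys),
             "rejected subgraph payload: finding carries forbidden field(s): ",
             paste(setdiff(names(f), fkeys), collapse = ", "))
  }
  findings <- if (length(doc$findings) == 0) {
    data.frame(date = character(0), hypernym_concept_id = character(0),
               positive = logical(0), stringsAsFactors = FALSE)
  } else {
    data.frame(date = vapply(doc$findings, `[[`, "", "date"),
               hypernym_concept_id = vapply(doc$findings, `[[`, "", "concept_id"),
               positive = vapply(doc$findings, `[[`, NA, "positive"),
               stringsAsFactors = FALSE)
  }
  build_online_subgraph(doc$patient_digest, findings,
                        visit_dates = unlist(doc$visits) %||% character(0),
                        origin = doc$origin, series = doc$series,
                        allowed_concepts = allowed_concepts %||%
                          unique(findings$hypernym_concept_id),
                        salt_id = doc$salt_id)
}

# ---- hash-chained ledger ---------------------------------------------------

GENESIS_PREV <- strrep("0", 64)

#' Create an empty ledger
#' @return object of class `ledger` (empty chain).
#' @export
ledger_new <- function() structure(list(blocks = list()), class = "ledger")

block_hash <- function(index, prev_hash, payload_hash)
  sha256_hex(paste(index, prev_hash, payload_hash, sep = "|"))

#' Append a payload to the ledger
#'
#' Extends the chain by one block: `block_hash = SHA-256(index | prev_hash |
#' payload_hash)`, with the genesis block chaining from 64 zeros. The tip link
#' is re-verified before appending.
#'
#' @param chain a `ledger`.
#' @param payload character scalar (serialized message: subgraph, ROI request,
#'   eligibility announcement, ...).
#' @return the extended `ledger`.
#' @export
ledger_append <- function(chain, payload) {
  abort_if(!is.character(payload) || length(payload) != 1,
           "ledger payload must be a character scalar")
  n <- length(chain$blocks)
  if (n == 0) {
    prev <- GENESIS_PREV; idx <- 0L
  } else {
    tip <- chain$blocks[[n]]
    abort_if(!identical(block_hash(tip$index, tip$prev_hash, tip$payload_hash),
                        tip$block_hash),
             "ledger tip fails verification; refusing to append")
    prev <- tip$block_hash; idx <- tip$index + 1L
  }
  ph <- sha256_hex(payload)
  chain$blocks[[n + 1L]] <- list(index = idx, prev_hash = prev, payload = payload,
                                 payload_hash = ph,
                                 block_hash = block_hash(idx, prev, ph))
  chain
}

#' Verify an entire ledger chain
#'
#' Recomputes every payload hash, every block hash and every prev-hash link.
#' Any single-byte mutation anywhere in the chain is detected.
#'
#' @param chain a `ledger`.
#' @return `TRUE` if the chain verifies; otherwise `FALSE` with attribute
#'   `first_invalid` naming the index of the first bad block.
#' @export
ledger_verify <- function(chain) {
  prev <- GENESIS_PREV
  for (b in chain$blocks) {
    ok <- identical(b$prev_hash, prev) &&
      identical(sha256_hex(b$payload), b$payload_hash) &&
      identical(block_hash(b$index, b$prev_hash, b$payload_hash), b$block_hash)
    if (!ok) return(structure(FALSE, first_invalid = b$index))
    prev <- b$block_hash
  }
  TRUE
}

#' Broadcast the chain to registered nodes
#'
#' Synchronous fan-out: every node receives the chain suffix starting at
#' `from_index` and acknowledges with a receipt carrying the process series
#' number.
#'
#' @param chain a verified `ledger`.
#' @param nodes character vector of node ids.
#' @param series process series number recorded on each receipt.
#' @param from_index first block index to deliver (default 0, the genesis).
#' @return delivery log data.frame: `node_id`, `from_index`, `to_index`,
#'   `tip_hash`, `series`.
#' @export
broadcast <- function(chain, nodes, series = NA_integer_, from_index = 0L) {
  ok <- ledger_verify(chain)
  abort_if(!isTRUE(ok), "tampered ledger: first invalid block ",
           attr(ok, "first_invalid"))
  n <- length(chain$blocks)
  tip <- if (n == 0) GENESIS_PREV else chain$blocks[[n]]$block_hash
  data.frame(node_id = nodes, from_index = from_index,
             to_index = if (n == 0) NA_integer_ else chain$blocks[[n]]$index,
             tip_hash = tip, series = as.integer(series),
             stringsAsFactors = FALSE)
}

#' Persist / load a ledger as JSON lines (one block per line)
#' @param chain a `ledger`.
#' @param path file path.
#' @return `path` (write) or a `ledger` (read).
#' @export
write_ledger <- function(chain, path) {
  lines <- vapply(chain$blocks, function(b)
    as.character(jsonlite::toJSON(b, auto_unbox = TRUE, digits = NA)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  blocks <- lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
  structure(list(blocks = lapply(blocks, function(b) {
    b$index <- as.integer(b$index); b
  })), class = "ledger")
}

#' All payloads carried by a ledger
#' @param chain a `ledger`.
#' @return character vector of payloads, in chain order.
#' @export
ledger_payloads <- function(chain)
  vapply(chain$blocks, `[[`, character(1), "payload")

# ---- merge -----------------------------------------------------------------

#' A per-patient merged pathway (local + virtual)
#'
#' @param digest patient identity digest.
#' @param visits data.frame `date` (Date), `origin`.
#' @param findings data.frame `date` (Date), `concept_id`, `positive`, `origin`.
#' @return object of class `merged_pathway`.
#' @export
merged_pathway <- function(digest,
                           visits = data.frame(date = as.Date(character(0)),
                                               origin = character(0)),
                           findings = data.frame(date = as.Date(character(0)),
                                                 concept_id = character(0),
                                                 positive = logical(0),
                                                 origin = character(0))) {
  structure(list(digest = digest,
                 visits = reset_rownames(unique(visits)),
                 findings = reset_rownames(unique(findings))),
            class = "merged_pathway")
}

#' Merge remote online subgraphs into a patient's pathway
#'
#' Attaches matching subgraphs' virtual visits and findings to the local
#' patient pathway with an origin tag; subgraphs for other patients are
#' ignored. Deduplication on (origin, date, concept, label) makes the merge
#' idempotent, and the merged timeline is the date-sorted union of local and
#' virtual visits.
#'
#' @param pathway a `merged_pathway` (typically seeded with local data).
#' @param subgraphs list of `online_subgraph` objects.
#' @return the merged `merged_pathway`.
#' @export
merge_remote <- function(pathway, subgraphs) {
  mine <- Filter(function(g) identical(g$patient_digest, pathway$digest), subgraphs)
  if (length(mine) == 0) return(pathway)
  v_new <- do.call(rbind, lapply(mine, function(g)
    if (length(g$visits) == 0) NULL else
      data.frame(date = as.Date(g$visits), origin = g$origin, stringsAsFactors = FALSE)))
  f_new <- do.call(rbind, lapply(mine, function(g)
    if (nrow(g$findings) == 0) NULL else
      data.frame(date = as.Date(g$findings$date), concept_id = g$findings$concept_id,
                 positive = g$findings$positive, origin = g$origin,
                 stringsAsFactors = FALSE)))
  visits <- unique(rbind(pathway$visits, v_new))
  findings <- unique(rbind(pathway$findings, f_new))
  merged_pathway(pathway$digest,
                 order_by(visits, c("date", "origin")),
                 order_by(findings, c("date", "concept_id", "origin", "positive")))
}
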