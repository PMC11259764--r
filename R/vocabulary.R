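# Concept vocabulary: a DAG of clinical concepts with designated hypernyms.
#
# The vocabulary is the semantic backbone of the system: EHR events reference
# leaf concepts, local reasoning produces leaf-level findings, and the privacy
# layer re-expresses those findings through more general hypernym concepts
# before anything leaves a hospital.

VALID_DOMAINS <- c("condition", "measurement", "drug", "procedure", "observation")

#' Build a concept graph from a concept table
#'
#' Validates and indexes a concept hierarchy: unique ids, resolvable parent
#' references, acyclicity, and the requirement that every concept flagged as a
#' hypernym has at least one descendant leaf (a hypernym that is itself a leaf
#' counts). Roots are concepts without parents; leaves are concepts without
#' children.
#'
#' @param concepts data.frame with columns `concept_id`, `name`, `domain`,
#'   `parent_ids` (list column or `|`-separated string) and `is_hypernym`
#'   (logical).
#' @param embeddings optional named list of numeric vectors (per concept_id),
#'   used for leaf cosine-similarity when selecting hypernym expressions.
#' @return object of class `concept_graph`.
#' @seealso [load_vocabulary()] to read the CSV interchange format.
#' @export
concept_graph <- function(concepts, embeddings = list()) {
  req <- c("concept_id", "name", "domain", "parent_ids", "is_hypernym")
  abort_if(!all(req %in% names(concepts)),
           "concept table must have columns: ", paste(req, collapse = ", "))
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  ids <- as.character(concepts$concept_id)
  dup <- ids[duplicated(ids)]
  abort_if(length(dup) > 0, "duplicate concept_id: ", paste(unique(dup), collapse = ", "))
  bad_dom <- setdiff(unique(concepts$domain), VALID_DOMAINS)
  abort_if(length(bad_dom) > 0, "unknown domain: ", paste(bad_dom, collapse = ", "))

  parents <- concepts$parent_ids
  if (!is.list(parents)) {
    parents <- lapply(as.character(parents), function(p) {
      if (is.na(p) || !nzchar(p)) character(0) else strsplit(p, "|", fixed = TRUE)[[1]]
    })
  }
  parents <- lapply(parents, as.character)
  names(parents) <- ids

  dangling <- setdiff(unique(unlist(parents)), ids)
  abort_if(length(dangling) > 0,
           "parent reference does not resolve: ", paste(dangling, collapse = ", "))

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)

  # Kahn topological sort over parent -> child edges; leftovers lie on a cycle
  indeg <- vapply(parents, length, integer(1))
  queue <- ids[indeg == 0L]
  topo <- character(0)
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  leftover <- setdiff(ids, topo)
  abort_if(length(leftover) > 0,
           "cycle detected in concept hierarchy involving concept: ", leftover[[1]])

  # depth = longest path from any root (roots at depth 0)
  depth <- stats::setNames(rep(0L, length(ids)), ids)
  for (v in topo) {
    ps <- parents[[v]]
    if (length(ps) > 0) depth[[v]] <- max(depth[ps]) + 1L
  }

  roots <- ids[vapply(parents, length, integer(1)) == 0L]
  leaves <- ids[vapply(children[ids], length, integer(1)) == 0L]

  if (length(embeddings) > 0) {
    bad <- setdiff(names(embeddings), ids)
    abort_if(length(bad) > 0, "embedding for unknown concept: ", paste(bad, collapse = ", "))
  }

  g <- structure(list(
    concepts = reset_rownames(data.frame(
      concept_id = ids, name = as.character(concepts$name),
      domain = as.character(concepts$domain),
      is_hypernym = as.logical(concepts$is_hypernym),
      stringsAsFactors = FALSE)),
    parents = parents, children = children,
    depth = depth, topo = topo, roots = roots, leaves = leaves,
    embeddings = embeddings
  ), class = "concept_graph")

  for (h in ids[g$concepts$is_hypernym]) {
    abort_if(length(descendant_leaves(g, h)) == 0,
             "hypernym concept has no descendant leaf: ", h)
  }
  g
}

#' Load a concept vocabulary from CSV
#'
#' Expected columns: `concept_id,name,domain,parent_ids,is_hypernym` with
#' `parent_ids` `|`-separated and an optional `embedding` column of
#' `;`-separated floats.
#'
#' @param path CSV file path.
#' @return a `concept_graph`.
#' @export
load_vocabulary <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(tab) == 0) {
    return(concept_graph(data.frame(concept_id = character(0), name = character(0),
                                    domain = character(0), parent_ids = character(0),
                                    is_hypernym = logical(0))))
  }
  emb <- list()
  if ("embedding" %in% names(tab)) {
    has <- !is.na(tab$embedding) & nzchar(tab$embedding)
    emb <- lapply(tab$embedding[has],
                  function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
    names(emb) <- tab$concept_id[has]
  }
  tab$is_hypernym <- toupper(tab$is_hypernym) %in% c("TRUE", "T", "1", "YES")
  concept_graph(tab, embeddings = emb)
}

#' Write a concept graph to the CSV interchange format
#' @param graph a `concept_graph`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(graph, path) {
  df <- graph$concepts
  df$parent_ids <- vapply(df$concept_id,
                          function(id) paste(graph$parents[[id]], collapse = "|"),
                          character(1))
  df$embedding <- vapply(df$concept_id, function(id) {
    e <- graph$embeddings[[id]]
    if (is.null(e)) "" else paste(format(e, trim = TRUE, scientific = FALSE), collapse = ";")
  }, character(1))
  utils::write.csv(df[c("concept_id", "name", "domain", "parent_ids",
                        "is_hypernym", "embedding")], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf("<concept_graph> %d concepts, %d roots, %d leaves, %d hypernyms\n",
              nrow(x$concepts), length(x$roots), length(x$leaves),
              sum(x$concepts$is_hypernym)))
  invisible(x)
}

has_concept <- function(graph, id) id %in% graph$concepts$concept_id

#' Ancestors of a concept
#' @param graph a `concept_graph`.
#' @param id concept id.
#' @param include_self include `id` itself in the result.
#' @return character vector of ancestor concept ids.
#' @export
concept_ancestors <- function(graph, id, include_self = FALSE) {
  abort_if(!has_concept(graph, id), "unknown concept: ", id)
  seen <- character(0)
  frontier <- graph$parents[[id]]
  while (length(frontier) > 0) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(graph$parents[new], use.names = FALSE))
  }
  if (include_self) unique(c(id, seen)) else unique(seen)
}

#' Descendant leaves of a concept
#'
#' A leaf concept is its own (sole) descendant leaf.
#' @inheritParams concept_ancestors
#' @return character vector of leaf concept ids under `id`.
#' @export
descendant_leaves <- function(graph, id) {
  abort_if(!has_concept(graph, id), "unknown concept: ", id)
  if (id %in% graph$leaves) return(id)
  out <- character(0)
  frontier <- graph$children[[id]]
  seen <- character(0)
  while (length(frontier) > 0) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    out <- c(out, intersect(new, graph$leaves))
    frontier <- unique(unlist(graph$children[new], use.names = FALSE))
  }
  unique(out)
}

#' Mean pairwise cosine similarity of a hypernym's descendant leaves
#'
#' Measures the semantic cohesion of the leaf set a hypernym would stand for.
#' Returns 1 when the hypernym covers exactly one leaf; otherwise averages the
#' cosine similarity over all unordered leaf pairs, using the leaf embeddings
#' stored in the graph.
#'
#' @param graph a `concept_graph` with embeddings for the relevant leaves.
#' @param hypernym concept id with at least one descendant leaf.
#' @return similarity in `[-1, 1]` (typically `[0, 1]` for non-negative
#'   embeddings).
#' @export
leaf_similarity <- function(graph, hypernym) {
  leaves <- descendant_leaves(graph, hypernym)
  abort_if(length(leaves) == 0, "hypernym has no descendant leaves: ", hypernym)
  if (length(leaves) == 1) return(1.0)
  missing <- leaves[vapply(leaves, function(l) is.null(graph$embeddings[[l]]), logical(1))]
  abort_if(length(missing) > 0,
           "leaf missing embedding (required for similarity): ",
           paste(missing, collapse = ", "))
  pairs <- utils::combn(leaves, 2)
  sims <- apply(pairs, 2, function(p)
    cosine_sim(graph$embeddings[[p[1]]], graph$embeddings[[p[2]]]))
  mean(sims)
}

#' Assign each leaf concept a hypernym expression
#'
#' For every leaf, chooses among its hypernym-flagged ancestors (a leaf that is
#' itself a hypernym is its own candidate) the most specific one — deepest in
#' the hierarchy — whose leaf cohesion ([leaf_similarity()]) reaches
#' `threshold`. If no candidate reaches the threshold the leaf falls back to
#' its most general hypernym ancestor and is recorded as low-cohesion: a
#' subtree whose leaves do not cohere is generalized conservatively rather than
#' narrowly. Leaves without any hypernym ancestor are left unmapped and
#' reported. Ties at equal depth break to the lexicographically smallest
#' concept id.
#'
#' @param graph a validated `concept_graph`.
#' @param threshold cohesion threshold in `[0, 1]` (default 0.7).
#' @return object of class `hypernym_map` with fields `entries` (named
#'   character vector leaf -> hypernym), `similarity_threshold`,
#'   `low_cohesion` and `unmapped` (character vectors of leaf ids).
#' @export
build_hypernym_map <- function(graph, threshold = 0.7) {
  abort_if(!is.numeric(threshold) || threshold < 0 || threshold > 1,
           "threshold must lie in [0, 1]")
  hyp_ids <- graph$concepts$concept_id[graph$concepts$is_hypernym]
  sim <- stats::setNames(vapply(hyp_ids, function(h) leaf_similarity(graph, h),
                                numeric(1)), hyp_ids)
  entries <- character(0); low <- character(0); unmapped <- character(0)
  for (leaf in sort(graph$leaves)) {
    cand <- intersect(concept_ancestors(graph, leaf, include_self = TRUE), hyp_ids)
    if (length(cand) == 0) { unmapped <- c(unmapped, leaf); next }
    pick_extreme <- function(set, deepest) {
      d <- graph$depth[set]
      best <- if (deepest) set[d == max(d)] else set[d == min(d)]
      sort(best)[[1]]
    }
    passing <- cand[sim[cand] >= threshold]
    if (length(passing) > 0) {
      entries[[leaf]] <- pick_extreme(passing, deepest = TRUE)
    } else {
      entries[[leaf]] <- pick_extreme(cand, deepest = FALSE)
      low <- c(low, leaf)
    }
  }
  structure(list(entries = entries, similarity_threshold = threshold,
                 low_cohesion = low, unmapped = unmapped),
            class = "hypernym_map")
}

#' @export
print.hypernym_map <- function(x, ...) {
  cat(sprintf("<hypernym_map> %d leaves mapped (threshold %.2f), %d low-cohesion, %d unmapped\n",
              length(x$entries), x$similarity_threshold,
              length(x$low_cohesion), length(x$unmapped)))
  invisible(x)
}
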