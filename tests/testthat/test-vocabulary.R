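test_that("vocabulary CSV round-trips through a validated DAG", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("concept_id,name,domain,parent_ids,is_hypernym,embedding",
               "root,kidney finding,observation,,FALSE,",
               "hyp_abn,abnormal kidney function,observation,root,TRUE,",
               "lf_g3b,eGFR G3b stage,observation,hyp_abn,FALSE,1;0"), path)
  g <- load_vocabulary(path)
  expect_s3_class(g, "concept_graph")
  expect_equal(g$roots, "root")
  expect_equal(g$leaves, "lf_g3b")
  # independent traversal: leaf reaches root through the hypernym
  expect_setequal(concept_ancestors(g, "lf_g3b"), c("hyp_abn", "root"))
  expect_equal(g$embeddings$lf_g3b, c(1, 0))

  out <- withr::local_tempfile(fileext = ".csv")
  write_vocabulary(g, out)
  g2 <- load_vocabulary(out)
  expect_equal(g2$concepts, g$concepts)
  expect_equal(g2$parents, g$parents)
})

test_that("empty vocabulary yields an empty graph", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("concept_id,name,domain,parent_ids,is_hypernym", path)
  g <- load_vocabulary(path)
  expect_equal(nrow(g$concepts), 0)
  expect_length(g$roots, 0)
})

test_that("structural defects are rejected with informative errors", {
  base <- data.frame(concept_id = c("A", "B"), name = c("a", "b"),
                     domain = "condition", parent_ids = c("B", "A"),
                     is_hypernym = FALSE, stringsAsFactors = FALSE)
  expect_error(concept_graph(base), "cycle")
  base$parent_ids <- c("", "missing")
  expect_error(concept_graph(base), "resolve")
  base$parent_ids <- ""
  base$concept_id <- c("A", "A")
  expect_error(concept_graph(base), "duplicate")
  # hypernym flag requires a descendant leaf is satisfied by a hypernym leaf
  solo <- data.frame(concept_id = "H", name = "h", domain = "condition",
                     parent_ids = "", is_hypernym = TRUE, stringsAsFactors = FALSE)
  expect_silent(concept_graph(solo))
})

test_that("leaf similarity is the mean pairwise cosine over descendant leaves", {
  expect_equal(leaf_similarity(tiny_vocab(), "hyp_k"), 1.0)
  g <- tiny_vocab(embeddings = list(lf_a = c(1, 0), lf_b = c(0, 1)))
  expect_equal(leaf_similarity(g, "hyp_k"), 0.0)

  # three leaves (1,0),(1,0),(0,1): pairs give {1, 0, 0} -> brute mean 1/3
  g3 <- concept_graph(data.frame(
    concept_id = c("r", "h", "l1", "l2", "l3"), name = letters[1:5],
    domain = "observation", parent_ids = c("", "r", "h", "h", "h"),
    is_hypernym = c(FALSE, TRUE, FALSE, FALSE, FALSE), stringsAsFactors = FALSE),
    embeddings = list(l1 = c(1, 0), l2 = c(1, 0), l3 = c(0, 1)))
  pairs <- combn(c("l1", "l2", "l3"), 2)
  brute <- mean(apply(pairs, 2, function(p) {
    e <- g3$embeddings
    sum(e[[p[1]]] * e[[p[2]]]) /
      (sqrt(sum(e[[p[1]]]^2)) * sqrt(sum(e[[p[2]]]^2)))
  }))
  expect_equal(leaf_similarity(g3, "h"), brute)
  expect_equal(leaf_similarity(g3, "h"), 1 / 3)

  # single-leaf hypernym needs no embedding; multi-leaf without embeddings errors
  g_nomb <- tiny_vocab(embeddings = list(lf_a = c(1, 0)))
  expect_error(leaf_similarity(g_nomb, "hyp_k"), "embedding")
})

test_that("hypernym map picks the most specific cohesive ancestor", {
  g <- tiny_vocab()
  m <- build_hypernym_map(g, threshold = 0.7)
  expect_equal(unname(m$entries["lf_a"]), "hyp_k")
  expect_equal(unname(m$entries["lf_b"]), "hyp_k")
  expect_length(m$unmapped, 0)

  # a leaf that is itself a hypernym maps to itself
  g2 <- concept_graph(data.frame(
    concept_id = c("r", "hl"), name = c("r", "hl"), domain = "observation",
    parent_ids = c("", "r"), is_hypernym = c(FALSE, TRUE),
    stringsAsFactors = FALSE))
  m2 <- build_hypernym_map(g2, threshold = 0.5)
  expect_equal(unname(m2$entries["hl"]), "hl")

  # deeper qualifying ancestor (depth 2) beats shallower one (depth 1)
  g3 <- concept_graph(data.frame(
    concept_id = c("r", "h_top", "h_mid", "leaf"), name = letters[1:4],
    domain = "observation", parent_ids = c("", "r", "h_top", "h_mid"),
    is_hypernym = c(FALSE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE),
    embeddings = list(leaf = c(1, 0)))
  m3 <- build_hypernym_map(g3, threshold = 0.9)
  expect_equal(unname(m3$entries["leaf"]), "h_mid")
})

test_that("hypernym map agrees with brute-force ancestor enumeration", {
  set.seed(402)
  for (rep in 1:8) {
    # random layered DAG <= 50 concepts with random hypernym flags
    n_h <- sample(2:5, 1); n_l <- sample(3:12, 1)
    ids <- c("root", sprintf("h%d", seq_len(n_h)), sprintf("l%d", seq_len(n_l)))
    parents <- c("", rep("root", n_h),
                 sprintf("h%d", sample.int(n_h, n_l, replace = TRUE)))
    emb <- lapply(seq_len(n_l), function(i) stats::runif(3))
    names(emb) <- sprintf("l%d", seq_len(n_l))
    g <- concept_graph(data.frame(concept_id = ids, name = ids,
                                  domain = "observation", parent_ids = parents,
                                  is_hypernym = c(FALSE, rep(TRUE, n_h), rep(FALSE, n_l)),
                                  stringsAsFactors = FALSE), embeddings = emb)
    thr <- stats::runif(1)
    m <- build_hypernym_map(g, thr)
    expect_identical(m$entries, brute_hypernym_map(g, thr))
    # mapped value is always an ancestor (or self) of the key
    for (leaf in names(m$entries))
      expect_true(m$entries[[leaf]] %in%
                    concept_ancestors(g, leaf, include_self = TRUE))
  }
})

test_that("raising the threshold never yields a more specific hypernym", {
  set.seed(77)
  for (rep in 1:6) {
    n_l <- sample(4:10, 1)
    ids <- c("root", "h1", "h2", sprintf("l%d", seq_len(n_l)))
    parents <- c("", "root", "h1", sprintf("h%d", sample(1:2, n_l, replace = TRUE)))
    emb <- lapply(seq_len(n_l), function(i) stats::runif(3))
    names(emb) <- sprintf("l%d", seq_len(n_l))
    emb$h2 <- stats::runif(3)  # h2 may itself be a leaf under h1
    g <- concept_graph(data.frame(concept_id = ids, name = ids,
                                  domain = "observation", parent_ids = parents,
                                  is_hypernym = c(FALSE, TRUE, TRUE, rep(FALSE, n_l)),
                                  stringsAsFactors = FALSE), embeddings = emb)
    thresholds <- sort(stats::runif(4))
    maps <- lapply(thresholds, function(t) build_hypernym_map(g, t))
    for (k in seq_along(maps)[-1]) {
      for (leaf in names(maps[[k]]$entries)) {
        d_hi <- g$depth[[maps[[k]]$entries[[leaf]]]]
        d_lo <- g$depth[[maps[[k - 1]]$entries[[leaf]]]]
        expect_lte(d_hi, d_lo)
      }
    }
  }
})

test_that("shipped vocabulary and rule files load to the built-in defaults", {
  vpath <- system.file("extdata", "ckd_vocabulary.csv", package = "fedkg")
  g <- load_vocabulary(vpath)
  ref <- default_ckd_vocabulary()
  expect_equal(g$concepts, ref$concepts)
  expect_equal(g$parents, ref$parents)
  expect_equal(g$embeddings[order(names(g$embeddings))],
               ref$embeddings[order(names(ref$embeddings))])
  rpath <- system.file("extdata", "ckd_rules.yaml", package = "fedkg")
  r <- read_ruleset(rpath)
  ref_r <- default_ckd_ruleset()
  expect_equal(r$measurement_rules, ref_r$measurement_rules)
  expect_equal(r$risk_hypernyms, ref_r$risk_hypernyms)
})
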