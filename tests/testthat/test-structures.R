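test_that("itemset containment and occurrence vectors follow the subset order", {
  ds <- toy_itemset()
  p1 <- spp_pattern(1L, "itemset")
  p12 <- spp_pattern(c(1L, 2L), "itemset")
  expect_true(spp_contains(p1, c(1L, 2L)))
  expect_false(spp_contains(p12, 1L))
  expect_equal(as.integer(occurrence_vector(p1, ds)), c(1L, 1L, 0L, 0L))
  expect_equal(as.integer(occurrence_vector(p12, ds)), c(0L, 1L, 0L, 0L))
  expect_equal(attr(occurrence_vector(p1, ds), "support"), c(1L, 2L))
})

test_that("sequence containment distinguishes gapped and contiguous modes", {
  vocab <- c("A", "B", "C")
  ds <- spp_dataset(list(c(1L, 2L, 3L)), 1, "sequence", vocab = vocab)
  p <- spp_pattern("AC", "sequence", vocab = vocab)
  expect_true(spp_contains(p, ds$instances[[1]], seq_mode = "gapped"))
  expect_false(spp_contains(p, ds$instances[[1]], seq_mode = "contiguous"))
  pbc <- spp_pattern("BC", "sequence", vocab = vocab)
  expect_true(spp_contains(pbc, ds$instances[[1]], seq_mode = "contiguous"))
  expect_equal(p$key, "A-C")
})

test_that("variant mismatch and empty datasets raise typed errors", {
  ds <- toy_itemset()
  p <- spp_pattern(1L, "itemset")
  expect_error(spp_contains(p, c(1L, 2L), type = "sequence"), "mismatch")
  expect_error(spp_dataset(list(), numeric(0), "itemset"), "empty")
})

test_that("graph containment agrees with exhaustive node-mapping search", {
  # single a-b edge inside a labeled triangle containing it
  tri <- list(vlab = c(1L, 2L, 3L),
              edges = cbind(c(1L, 2L, 1L), c(2L, 3L, 3L), c(1L, 1L, 2L)))
  p <- spp_pattern(list(vlab = c(1L, 2L), edges = cbind(1L, 2L, 1L)), "graph")
  g <- sppmine:::as_spp_graph(tri)
  expect_true(spp_contains(p, g))
  # random graphs up to 6 nodes, random small patterns
  set.seed(7)
  sy <- small_synth("graph", seed = 4, n = 15)
  ds <- sy$dataset
  pats <- enumerate_patterns(ds, 2)
  for (j in seq_len(min(nrow(pats), 12))) {
    p <- pats$pattern[[j]]
    for (i in seq_len(6)) {
      expect_identical(
        spp_contains(p, ds$instances[[i]]),
        brute_graph_contains(p$graph, ds$instances[[i]]),
        info = sprintf("pattern %s instance %d", p$key, i))
    }
  }
})

test_that("itemset enumeration is complete, unique and in canonical order", {
  ds <- toy_itemset()
  ep <- enumerate_patterns(ds, 3)
  expect_equal(ep$key, c("1", "1,2", "2"))  # DFS canonical order
  # brute force: all subsets of the universe occurring in >= 1 instance
  sy <- small_synth("itemset", seed = 9)
  ds2 <- sy$dataset
  ep2 <- enumerate_patterns(ds2, 3)
  expect_false(anyDuplicated(ep2$key) > 0)
  universe <- sort(unique(unlist(ds2$instances)))
  brute <- character(0)
  for (k in 1:3) {
    for (s in utils::combn(universe, k, simplify = FALSE)) {
      if (any(vapply(ds2$instances, function(x) all(s %in% x), logical(1)))) {
        brute <- c(brute, paste(s, collapse = ","))
      }
    }
  }
  expect_setequal(ep2$key, brute)
})

test_that("gapped-sequence enumeration matches the naive containment oracle", {
  sy <- small_synth("sequence", seed = 5, n = 15)
  ds <- sy$dataset
  ep <- enumerate_patterns(ds, 2)
  expect_false(anyDuplicated(ep$key) > 0)
  # every enumerated support matches a per-instance contains() loop
  for (j in seq_len(nrow(ep))) {
    occ <- occurrence_vector(ep$pattern[[j]], ds, seq_mode = "gapped")
    expect_equal(ep$support[[j]], attr(occ, "support"), info = ep$key[j])
  }
  # completeness at size 1 and 2 against brute force over the alphabet
  ab <- sort(unique(unlist(ds$instances)))
  brute <- character(0)
  for (a in ab) for (b in c(NA, ab)) {
    p <- if (is.na(b)) a else c(a, b)
    if (any(vapply(ds$instances, function(s) sppmine:::is_subsequence(p, s),
                   logical(1)))) {
      brute <- c(brute, paste(ds$vocab[p], collapse = "-"))
    }
  }
  expect_setequal(ep$key, brute)
})

test_that("subgraph enumeration yields each isomorphism class exactly once", {
  sy <- small_synth("graph", seed = 3, n = 10)
  ds <- sy$dataset
  ep <- enumerate_patterns(ds, 3)
  expect_false(anyDuplicated(ep$key) > 0)
  classes <- brute_subgraph_classes(ds, 3)
  expect_equal(nrow(ep), length(classes))
  # every enumerated pattern is isomorphic to exactly one brute-force class
  matched <- logical(length(classes))
  for (j in seq_len(nrow(ep))) {
    hits <- which(vapply(classes, graphs_isomorphic,
                         logical(1), g2 = ep$pattern[[j]]$graph))
    expect_length(hits, 1L)
    matched[hits] <- TRUE
  }
  expect_true(all(matched))
})

test_that("supports shrink monotonically along every tree edge", {
  for (type in c("itemset", "sequence", "graph")) {
    sy <- small_synth(type, seed = 21, n = 15)
    expect_true(check_support_monotone(sy$dataset, 3), info = type)
  }
  sy <- small_synth("sequence", seed = 22, n = 15)
  expect_true(check_support_monotone(sy$dataset, 3, seq_mode = "contiguous"))
})

test_that("children extend canonically from the toy root", {
  ds <- toy_itemset()
  lvl1 <- character(0)
  sppmine:::pattern_tree_dfs(ds, 1, function(node) {
    lvl1 <<- c(lvl1, sppmine:::body_key(node$type, node$body))
    TRUE
  })
  expect_equal(lvl1, c("1", "2"))
  # {1}'s children over a universe where both extensions occur
  ds2 <- spp_dataset(list(c(1L, 2L), c(1L, 3L)), c(0, 1), "itemset")
  keys <- character(0)
  sppmine:::pattern_tree_dfs(ds2, 2, function(node) {
    keys <<- c(keys, sppmine:::body_key(node$type, node$body))
    TRUE
  })
  expect_true(all(c("1,2", "1,3") %in% keys))
})

test_that("minimum DFS codes are canonical keys for isomorphism classes", {
  # the same labeled graph under vertex relabelings has one minimum code
  base <- list(vlab = c(1L, 1L, 2L, 3L),
               edges = rbind(c(1L, 2L, 5L), c(2L, 3L, 6L),
                             c(1L, 3L, 6L), c(3L, 4L, 5L)))
  set.seed(1)
  codes <- lapply(1:4, function(i) {
    pp <- sample(4L)
    vl <- integer(4L); vl[pp] <- base$vlab
    ed <- cbind(matrix(pp[base$edges[, 1:2]], ncol = 2L), base$edges[, 3L])
    sppmine:::min_dfs_code(sppmine:::as_spp_graph(list(vlab = vl, edges = ed)))
  })
  for (i in 2:4) expect_identical(codes[[1]], codes[[i]])
})
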