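# Path reconstruction, tree merging, roles, pruning and the path audit.

junction_state <- function(seed = 1) {
  tab <- gen_junction(n = 5000, eps = 0.2, seed = seed)
  list(tab = tab, st = searched_state(tab, seed = seed))
}

test_that("junction paths reconstruct the generating topology", {
  js <- junction_state(1)
  p <- with_seed_reconstruct <- reconstruct_path(js$st, "A3")
  expect_identical(p$features, c("Y", "A1", "A2", "J", "A3"))
  expect_gt(p$score, 0)
  # depth-1 features head initial pairs but never terminate a path
  expect_null(reconstruct_path(js$st, "A1"))
  expect_null(reconstruct_path(js$st, "B1"))
  expect_error(reconstruct_path(js$st, "Y"), "anchor")
})

test_that("terminals are absent on independent data", {
  tab <- gen_independent(m = 5, n = 800, seed = 3)
  st <- searched_state(tab, seed = 3)
  tr <- prune_tree(build_tree(st, seed = 3), 0.01)
  expect_identical(length(tr$paths), 0L)
  expect_true(all(tr$roles == "absent"))
})

test_that("the junction tree represents the bi-modality of the junction", {
  js <- junction_state(2)
  tr <- build_tree(js$st, seed = 2)
  nd <- tr$nodes
  # J appears as two distinct pair-nodes, one per branch
  jn <- nd[nd$feature == "J", ]
  expect_identical(sort(jn$prev_feature), c("A2", "B2"))
  # both deep terminals route through J
  expect_true("J" %in% tr$paths[["A3"]]$features)
  expect_true("J" %in% tr$paths[["B3"]]$features)
  # depth-1 features are relays only
  expect_identical(unname(tr$roles[c("A1", "B1")]), c("relay", "relay"))
})

test_that("a single noisy chain yields one path with correct roles", {
  tab <- gen_chain(depth = 3, branching = 1, n = 2000, eps = 0.1, seed = 6)
  st <- searched_state(tab, seed = 6)
  O <- oracle_pair_scores(tab)
  expect_lt(max(abs(st$S - unname(O))), 1e-12)
  tr <- build_tree(st, seed = 6)
  expect_identical(tr$paths[["C1_3"]]$features, c("Y", "C1_1", "C1_2", "C1_3"))
  expect_identical(unname(tr$roles["C1_1"]), "relay")
  expect_identical(unname(tr$roles["C1_3"]), "leaf")
})

test_that("an unsearched empty state produces an empty tree", {
  tab <- gen_chain(depth = 2, branching = 2, n = 100, eps = 0, seed = 2)
  st <- run_search(init_scores(tab))
  tr <- build_tree(st)
  expect_identical(nrow(tr$nodes), 0L)
  expect_identical(length(tr$paths), 0L)
})

test_that("pruning applies the inclusive threshold and is idempotent", {
  js <- junction_state(3)
  tr <- build_tree(js$st, seed = 3)

  expect_identical(prune_tree(tr, 0)$paths, tr$paths)
  expect_identical(length(prune_tree(tr, 1e9)$paths), 0L)

  # inclusive rule on a hand-built tree with scores 0.05 / 0.02 / 0.01
  paths <- list(
    P1 = structure(list(features = c("Y", "a", "b"), score = 0.05,
                        terminal = "b"), class = "influence_path"),
    P2 = structure(list(features = c("Y", "a", "c"), score = 0.02,
                        terminal = "c"), class = "influence_path"),
    P3 = structure(list(features = c("Y", "d", "e"), score = 0.01,
                        terminal = "e"), class = "influence_path"))
  toy <- infotrail:::new_tree(paths, c("a", "b", "c", "d", "e"), "Y")
  kept <- prune_tree(toy, 0.02)
  expect_identical(names(kept$paths), c("P1", "P2"))
  # relays survive only on surviving paths
  expect_identical(unname(kept$roles["d"]), "absent")

  # idempotence and monotonicity
  expect_identical(prune_tree(prune_tree(tr, 0.02), 0.02)$paths,
                   prune_tree(tr, 0.02)$paths)
  s1 <- names(prune_tree(tr, 0.03)$paths)
  s2 <- names(prune_tree(tr, 0.01)$paths)
  expect_true(all(s1 %in% s2))
})

test_that("a feature is a leaf in at most one path", {
  for (s in c(4, 5)) {
    js <- junction_state(s)
    tr <- build_tree(js$st, seed = s)
    leaves <- tr$nodes$id[tr$nodes$role == "leaf"]
    expect_identical(length(leaves), length(tr$paths))
    terminal_feats <- vapply(tr$paths, function(p) p$terminal, "")
    expect_identical(anyDuplicated(terminal_feats), 0L)
  }
})

test_that("every emitted path passes the independent criteria audit", {
  js <- junction_state(6)
  tr <- build_tree(js$st, seed = 6)
  aud <- audit_paths(tr, js$tab, "mle")
  expect_gt(nrow(aud), 0)
  expect_true(all(aud$dpi_anchor))
  expect_true(all(aud$dpi_local))
  expect_true(all(aud$min_ii_positive))
  expect_true(all(aud$score_consistent))

  # and no path revisits a feature (acyclicity via the anchor-DPI gate)
  for (p in tr$paths)
    expect_identical(anyDuplicated(p$features), 0L)
})

test_that("tree scores are non-increasing along every root-to-leaf walk", {
  js <- junction_state(7)
  tr <- build_tree(js$st, seed = 7)
  nd <- tr$nodes
  for (i in seq_len(nrow(nd))) {
    par <- nd$parent[i]
    if (identical(par, "")) next
    expect_lte(nd$score[i], nd$score[match(par, nd$id)] + 1e-15)
  }
})
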