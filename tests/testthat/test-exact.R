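test_that("spanning-tree enumeration recovers the known tree sets", {
  g <- iffl()
  trees <- enumerate_spanning_trees(g)
  expect_length(trees, 3L)
  # edges are rows of g$edges: 1 = A->B, 2 = A->C, 3 = B-|C
  expect_same_tree_set(trees, list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))

  # a tree graph's only spanning tree is itself
  tr <- random_signed_graph(6, 5, seed = 3)
  expect_equal(enumerate_spanning_trees(tr), list(1:5))

  # complete graph on 4 nodes: Cayley 4^2 = 16 trees
  pairs <- t(utils::combn(LETTERS[1:4], 2))
  k4 <- signed_graph(data.frame(source = pairs[, 1], target = pairs[, 2],
                                sign = 1L), reference = "A")
  expect_length(enumerate_spanning_trees(k4), 16L)
  expect_equal(count_spanning_trees(k4), 16)

  # parallel contradictory edges give distinct trees
  expect_length(enumerate_spanning_trees(parallel_graph()), 2L)
  expect_equal(count_spanning_trees(parallel_graph()), 2)

  single <- signed_graph(NULL, reference = "R")
  expect_equal(count_spanning_trees(single), 1)
  expect_equal(enumerate_spanning_trees(single), list(integer(0)))

  expect_error(enumerate_spanning_trees(k4, cap = 10), "cap")
})

test_that("matrix-tree count, contraction-deletion and subset brute force agree on random graphs", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(3:8, 1)
    m <- sample((n - 1):min(choose(n, 2), n + 3), 1)
    g <- random_signed_graph(n, m, p_negative = 0.3, seed = seed)
    trees <- enumerate_spanning_trees(g)
    expect_equal(length(trees), count_spanning_trees(g))
    expect_same_tree_set(trees, brute_force_trees(g))
    # each enumerated tree is spanning, acyclic and balanced
    for (t in trees) {
      expect_length(t, n - 1L)
      s <- tree_signs(g, t)
      expect_true(all(s %in% c(-1L, 1L)))
      eu <- match(g$edges$source[t], g$nodes)
      ev <- match(g$edges$target[t], g$nodes)
      expect_true(all(s[eu] * s[ev] == g$edges$sign[t]))
    }
  }
})

test_that("tree path signs multiply edge signs along the unique path", {
  g <- iffl()
  expect_equal(tree_signs(g, c(1L, 3L)), c(A = 1L, B = 1L, C = -1L))
  expect_equal(tree_signs(g, c(2L, 3L)), c(A = 1L, B = -1L, C = 1L))
  expect_equal(tree_signs(g, c(1L, 2L)), c(A = 1L, B = 1L, C = 1L))
  expect_error(tree_signs(g, c(1L, 2L, 3L)), "spanning tree")

  ch <- chain_graph()
  expect_equal(tree_signs(ch, 1:2), c(A = 1L, B = 1L, C = -1L))
})

test_that("exact effective weights match printed and brute-force values", {
  w <- exact_effective_weights(iffl())
  expect_equal(w$S, c(A = 1, B = 1 / 3, C = 1 / 3))
  expect_identical(w$exact, TRUE)
  expect_equal(unname(w$n_plus + w$n_minus), rep(3, 3))

  # balanced graphs: weights equal propagated signs bit-exactly
  for (seed in 1:5) {
    g <- balanced_random_graph(7, 10, seed = seed)
    b <- check_balance(g)
    expect_identical(unname(exact_effective_weights(g)$S),
                     as.numeric(b$node_signs))
  }

  # 4-cycle with one negative edge, derived by averaging the 4 per-tree
  # sign vectors by hand (and cross-checked against the subset oracle)
  g4 <- four_cycle_graph()
  w4 <- exact_effective_weights(g4)
  expect_equal(w4$S, c(A = 1, B = 1 / 2, C = 0, D = 1 / 2))
  oracle <- brute_force_trees(g4)
  S_oracle <- rowMeans(vapply(oracle, function(t) tree_signs(g4, t),
                              integer(4)))
  expect_equal(unname(w4$S), unname(S_oracle))
})

test_that("per-tree scores match printed values and the node-sum identity", {
  g <- iffl()
  trees <- enumerate_spanning_trees(g)
  x1 <- c(A = 1, B = 1, C = 1)
  expect_equal(vapply(trees, function(t) tree_score(g, t, x1), numeric(1)),
               c(3, 1, 1))
  expect_equal(vapply(trees, function(t) tree_score(g, t, c(A = 0, B = 0,
                                                            C = 0)),
                      numeric(1)), c(0, 0, 0))
  expect_equal(tree_score(g, c(1L, 3L), c(A = 1, B = 2, C = 0)), 3)

  # mean of per-tree scores equals the weight-aggregated sum (swap of the
  # two summations), on random graphs and scores
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:7, 1)
    g <- random_signed_graph(n, min(choose(n, 2), n + 2), p_negative = 0.4,
                             seed = seed)
    x <- random_scores(g$nodes, "gaussian", seed = seed)
    trees <- enumerate_spanning_trees(g)
    mean_trees <- mean(vapply(trees, function(t) tree_score(g, t, x),
                              numeric(1)))
    expect_equal(mean_trees, aggregate_scores(exact_effective_weights(g), x),
                 tolerance = 1e-12)
  }
})

test_that("line index of balance is the minimal balancing deletion count", {
  res <- line_index_of_balance(iffl())
  expect_equal(res$z, 1L)
  expect_equal(nrow(res$edges), 1L)

  expect_equal(line_index_of_balance(chain_graph())$z, 0L)
  expect_equal(nrow(line_index_of_balance(chain_graph())$edges), 0L)

  # two negative triangles joined by a bridge: one deletion per triangle
  tri2 <- signed_graph(data.frame(
    source = c("A", "B", "C", "C", "D", "E", "F"),
    target = c("B", "C", "A", "D", "E", "F", "D"),
    sign   = c(1L, 1L, -1L, 1L, 1L, 1L, -1L)), reference = "A")
  expect_false(check_balance(tri2)$balanced)
  expect_equal(line_index_of_balance(tri2)$z, 2L)

  # z = 0 iff balanced, on random graphs
  for (seed in 1:10) {
    g <- random_signed_graph(6, 8, p_negative = 0.3, seed = seed)
    expect_identical(line_index_of_balance(g)$z == 0L,
                     check_balance(g)$balanced)
  }

  big <- random_signed_graph(12, 40, p_negative = 0.5, seed = 1,
                             force_unbalanced = TRUE)
  expect_error(line_index_of_balance(big, cap = 50), "cap")
})
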