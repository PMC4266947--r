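test_that("constructor normalizes edges: loops dropped, duplicates collapsed, contradictions kept", {
  expect_warning(
    g <- signed_graph(data.frame(source = c("A", "B"), target = c("A", "A"),
                                 sign = c(1L, 1L)), reference = "A"),
    "self-loop")
  expect_equal(nrow(g$edges), 1L)

  expect_warning(
    g2 <- signed_graph(data.frame(source = c("A", "A"), target = c("B", "B"),
                                  sign = c(1L, 1L)), reference = "A"),
    "duplicate")
  expect_equal(nrow(g2$edges), 1L)

  # same endpoints, opposite signs: retained as parallel edges
  g3 <- parallel_graph()
  expect_equal(nrow(g3$edges), 2L)
  expect_setequal(g3$edges$sign, c(-1L, 1L))

  expect_error(signed_graph(data.frame(source = "A", target = "B", sign = 2),
                            reference = "A"), "sign")
  expect_error(signed_graph(data.frame(source = "A", target = "B", sign = 1,
                                       edge_class = "bogus"),
                            reference = "A"), "edge class")
})

test_that("edge-list files round-trip through the tsv and sif dialects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#ref\tA", "# a comment", "A\t->\tB", "A\t->\tC", "B\t-|\tC"),
             path)
  g <- read_signed_graph(path)
  expect_equal(sort(g$nodes), c("A", "B", "C"))
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$reference, "A")
  expect_false(check_balance(g)$balanced)

  # word relations and per-edge classes
  writeLines(c("A\tincreases\tB\texpression", "B\tdecreases\tC"), path)
  g2 <- read_signed_graph(path, reference = "A")
  expect_equal(g2$edges$sign, c(1L, -1L))
  expect_equal(g2$edges$edge_class, c("expression", "default"))
  expect_equal(g2$edges$traversal_weight, c(1 / 4, 1))

  writeLines(c("A\tactivates\tB", "B\tinhibits\tC"), path)
  expect_error(read_signed_graph(path, reference = "A"), "unknown relation")
  g3 <- read_signed_graph(path, reference = "A", dialect = "sif")
  expect_equal(g3$edges$sign, c(1L, -1L))

  # writer emits a file the reader reproduces
  out <- withr::local_tempfile(fileext = ".tsv")
  write_signed_graph(g, out)
  g4 <- read_signed_graph(out)
  expect_equal(g4$edges[, c("source", "target", "sign")],
               g$edges[, c("source", "target", "sign")])
})

test_that("degenerate and malformed inputs are handled at parse time", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#ref\tA", path)
  g <- read_signed_graph(path)       # single declared node, no edges
  expect_equal(g$nodes, "A")
  expect_equal(nrow(g$edges), 0L)

  writeLines(c("#ref\tA", "A\t-?\tB"), path)
  expect_error(read_signed_graph(path), "unknown relation token '-\\?'")
  writeLines("A\t->\tB", path)
  expect_error(read_signed_graph(path), "reference")
})

test_that("node score files parse with and without a header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node\tscore", "A\t1.5", "B\t-2"), path)
  expect_equal(read_node_scores(path), c(A = 1.5, B = -2))
  writeLines(c("A\t1.5", "B\t-2"), path)
  expect_equal(read_node_scores(path), c(A = 1.5, B = -2))
})

test_that("balance verdicts and witnesses are correct on known motifs", {
  rep_iffl <- check_balance(iffl())
  expect_false(rep_iffl$balanced)
  expect_equal(prod(rep_iffl$witness_cycle$sign), -1)
  expect_equal(nrow(rep_iffl$witness_cycle), 3L)   # the whole incoherent loop

  rep_chain <- check_balance(chain_graph())
  expect_true(rep_chain$balanced)
  expect_equal(rep_chain$node_signs, c(A = 1L, B = 1L, C = -1L))

  # incoherent loop made coherent: B -| C replaced by B -> C
  coherent <- signed_graph(data.frame(source = c("A", "A", "B"),
                                      target = c("B", "C", "C"),
                                      sign = c(1L, 1L, 1L)), reference = "A")
  rep_coh <- check_balance(coherent)
  expect_true(rep_coh$balanced)
  expect_equal(unname(rep_coh$node_signs), c(1L, 1L, 1L))

  disconnected <- signed_graph(data.frame(source = "A", target = "B",
                                          sign = 1L),
                               reference = "A", nodes = c("A", "B", "Z"))
  expect_error(check_balance(disconnected), "connected")
  expect_equal(sort(reference_component(disconnected)$nodes), c("A", "B"))
})

test_that("switching a node's incident edge signs never changes the balance verdict", {
  for (seed in 1:20) {
    g <- random_signed_graph(7, 10, p_negative = 0.4, seed = seed)
    verdict <- check_balance(g)$balanced
    set.seed(seed)
    v <- sample(g$nodes, 1)
    e <- g$edges
    k <- (e$source == v) + (e$target == v)
    e$sign <- e$sign * ifelse(k == 1L, -1L, 1L)
    g_sw <- signed_graph(e[, c("source", "target", "sign", "edge_class")],
                         reference = g$reference, nodes = g$nodes)
    expect_identical(check_balance(g_sw)$balanced, verdict)
  }
})

test_that("trees are always balanced; flipping one cycle edge of a balanced graph unbalances it", {
  for (seed in 1:10) {
    tr <- random_signed_graph(8, 7, p_negative = 0.5, seed = seed)
    expect_true(check_balance(tr)$balanced)

    g <- balanced_random_graph(8, 12, seed = seed)
    expect_true(check_balance(g)$balanced)
    # an edge on a cycle: any edge whose removal keeps the graph connected
    e <- g$edges
    on_cycle <- which(vapply(seq_len(nrow(e)), function(k) {
      is_connected(signed_graph(e[-k, c("source", "target", "sign",
                                        "edge_class")],
                                reference = g$reference, nodes = g$nodes))
    }, logical(1)))
    k <- on_cycle[1L]
    e$sign[k] <- -e$sign[k]
    g_flip <- signed_graph(e[, c("source", "target", "sign", "edge_class")],
                           reference = g$reference, nodes = g$nodes)
    expect_false(check_balance(g_flip)$balanced)
  }
})

test_that("balanced aggregation matches hand values and rejects bad input", {
  expect_equal(aggregate_balanced(chain_graph(), c(A = 1, B = 1, C = 1)), 1)
  expect_equal(aggregate_balanced(chain_graph(), c(A = 0, B = 0, C = 0)), 0)
  single <- signed_graph(NULL, reference = "R")
  expect_equal(aggregate_balanced(single, c(R = 2.5)), 2.5)
  expect_error(aggregate_balanced(iffl(), c(A = 1, B = 1, C = 1)),
               "unbalanced")
  expect_error(aggregate_balanced(chain_graph(), c(A = 1, B = 1)),
               "no score for node")
  expect_equal(aggregate_balanced(chain_graph(), c(A = 1, B = 1),
                                  impute_zero = TRUE), 2)
})

test_that("balanced aggregation is propagation-path invariant", {
  # aggregate computed from signs propagated within random spanning trees
  # equals the full-graph BFS aggregate
  for (seed in 1:10) {
    g <- balanced_random_graph(9, 14, seed = seed)
    x <- random_scores(g$nodes, "gaussian", seed = seed)
    ref_val <- aggregate_balanced(g, x)
    sam <- sample_spanning_trees(g, n_trees = 5, seed = seed)
    for (t in sam$trees)
      expect_equal(sum(tree_signs(g, t) * x[g$nodes]), ref_val)
  }
})
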