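# shared fixture builders and independent oracles; everything is generated in
# code so no data files ship with the tests

# balanced chain A -> B -| C, reference A: signs (A, B, C) = (+1, +1, -1)
chain_graph <- function() {
  signed_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
                          sign = c(1L, -1L)), reference = "A")
}

# 4-cycle A -> B -> C -| D -> A with a single negative edge
four_cycle_graph <- function() {
  signed_graph(data.frame(source = c("A", "B", "C", "D"),
                          target = c("B", "C", "D", "A"),
                          sign = c(1L, 1L, -1L, 1L)), reference = "A")
}

# two nodes joined by contradictory parallel edges (a 2-cycle with sign -1)
parallel_graph <- function() {
  signed_graph(data.frame(source = c("A", "A"), target = c("B", "B"),
                          sign = c(1L, -1L)), reference = "A")
}

# balanced connected graph with mixed signs: start all-positive (trivially
# balanced), then switch a random node subset (flip every edge with exactly
# one endpoint in the subset), which preserves balance
balanced_random_graph <- function(n_nodes, n_edges, seed) {
  g <- random_signed_graph(n_nodes, n_edges, p_negative = 0, seed = seed)
  set.seed(seed)
  flip <- sample(g$nodes, max(1L, n_nodes %/% 3L))
  e <- g$edges
  k <- (e$source %in% flip) + (e$target %in% flip)
  e$sign <- e$sign * ifelse(k == 1L, -1L, 1L)
  signed_graph(e[, c("source", "target", "sign", "edge_class")],
               reference = g$reference, nodes = g$nodes)
}

# independent spanning-tree oracle: filter all (n-1)-edge subsets for
# acyclic spanning ones via union-find; deliberately unrelated to the
# package's contraction-deletion enumerator
brute_force_trees <- function(graph) {
  n <- length(graph$nodes)
  m <- nrow(graph$edges)
  if (n == 1L) return(list(integer(0)))
  eu <- match(graph$edges$source, graph$nodes)
  ev <- match(graph$edges$target, graph$nodes)
  is_tree <- function(idx) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (k in idx) {
      a <- find(eu[k]); b <- find(ev[k])
      if (a == b) return(FALSE)
      parent[a] <- b
    }
    TRUE
  }
  subs <- utils::combn(m, n - 1L)
  out <- list()
  for (j in seq_len(ncol(subs)))
    if (is_tree(subs[, j])) out[[length(out) + 1L]] <- subs[, j]
  out
}

tree_key <- function(tree) paste(sort(tree), collapse = "-")

expect_same_tree_set <- function(a, b) {
  expect_setequal(vapply(a, tree_key, character(1)),
                  vapply(b, tree_key, character(1)))
}
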