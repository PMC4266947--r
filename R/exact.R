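#' Count spanning trees by the matrix-tree theorem
#'
#' The number of spanning trees of a connected multigraph equals any cofactor
#' of its Laplacian (Kirchhoff's matrix-tree theorem), with the adjacency
#' entries counting parallel edges. The determinant is computed with the
#' fraction-free Bareiss elimination so every intermediate value is an
#' integer; counts are exact as long as they stay below 2^53, far above the
#' enumeration cap this package supports.
#'
#' @param graph a connected [signed_graph()]; edge signs and directions are
#'   irrelevant to the count.
#' @return the number of spanning trees, as a double holding an exact integer.
#' @examples
#' count_spanning_trees(iffl())   # 3
#' @export
count_spanning_trees <- function(graph) {
  stop_if_disconnected(graph, "count_spanning_trees")
  gi <- graph_index(graph)
  if (gi$n == 1L) return(1)
  A <- matrix(0, gi$n, gi$n)
  for (k in seq_along(gi$eu)) {
    A[gi$eu[k], gi$ev[k]] <- A[gi$eu[k], gi$ev[k]] + 1
    A[gi$ev[k], gi$eu[k]] <- A[gi$ev[k], gi$eu[k]] + 1
  }
  L <- diag(rowSums(A)) - A
  bareiss_det(L[-gi$ref, -gi$ref, drop = FALSE])
}

# fraction-free determinant (Bareiss); exact for integer matrices while all
# intermediates stay below 2^53
bareiss_det <- function(M) {
  n <- nrow(M)
  if (n == 0L) return(1)
  sign <- 1
  prev <- 1
  for (k in seq_len(n - 1L)) {
    if (M[k, k] == 0) {
      piv <- which(M[(k + 1):n, k] != 0)
      if (!length(piv)) return(0)
      r <- k + piv[1L]
      tmp <- M[k, ]; M[k, ] <- M[r, ]; M[r, ] <- tmp
      sign <- -sign
    }
    idx <- (k + 1):n
    M[idx, idx] <- (M[idx, idx] * M[k, k] -
                      M[idx, k, drop = FALSE] %*% M[k, idx, drop = FALSE]) / prev
    prev <- M[k, k]
  }
  sign * M[n, n]
}

#' Enumerate all spanning trees of a small graph
#'
#' Exhaustive enumeration by contraction-deletion recursion: the spanning
#' trees of a multigraph partition into those containing a pivot edge (the
#' trees of the graph with that edge contracted) and those avoiding it (the
#' trees of the graph with it deleted). Parallel edges are distinct tree
#' members. Enumeration order is deterministic for a fixed edge ordering.
#'
#' This is the exact oracle behind [exact_effective_weights()]; it refuses
#' graphs whose matrix-tree count exceeds `cap`, the regime the Monte-Carlo
#' sampler ([estimate_effective_weights()]) exists for.
#'
#' @param graph a connected [signed_graph()].
#' @param cap refuse when the number of spanning trees exceeds this.
#' @return list of spanning trees, each an integer vector of edge indices
#'   (rows of `graph$edges`), sorted increasingly within each tree.
#' @examples
#' enumerate_spanning_trees(iffl())   # the 3 trees of the incoherent loop
#' @export
enumerate_spanning_trees <- function(graph, cap = 1e6) {
  stop_if_disconnected(graph, "enumerate_spanning_trees")
  total <- count_spanning_trees(graph)
  if (total > cap)
    stop("graph has ", format(total, big.mark = ","), " spanning trees, above ",
         "the enumeration cap (", format(cap, big.mark = ","), "); use the ",
         "sampler (estimate_effective_weights / sst) instead", call. = FALSE)
  gi <- graph_index(graph)
  n <- gi$n
  if (n == 1L) return(list(integer(0)))

  out <- vector("list", total)
  n_found <- 0L

  connected_quotient <- function(comp, avail) {
    labs <- unique(comp)
    if (length(labs) == 1L) return(TRUE)
    cc <- node_components(length(comp), comp[gi$eu[avail]], comp[gi$ev[avail]])
    length(unique(cc[labs])) == 1L
  }

  recurse <- function(comp, avail, chosen) {
    if (length(unique(comp)) == 1L) {
      n_found <<- n_found + 1L
      out[[n_found]] <<- sort(chosen)
      return(invisible(NULL))
    }
    nonloop <- avail[comp[gi$eu[avail]] != comp[gi$ev[avail]]]
    if (!length(nonloop)) return(invisible(NULL))
    e <- nonloop[1L]
    rest <- avail[avail != e]
    # include e: contract its endpoints
    comp2 <- comp
    comp2[comp2 == comp[gi$ev[e]]] <- comp[gi$eu[e]]
    recurse(comp2, rest, c(chosen, e))
    # exclude e: only if the remainder still connects all supernodes
    if (connected_quotient(comp, rest[comp[gi$eu[rest]] != comp[gi$ev[rest]]]))
      recurse(comp, rest, chosen)
    invisible(NULL)
  }

  recurse(seq_len(n), seq_along(gi$eu), integer(0))
  stopifnot(n_found == total)
  out
}

#' Path signs of every node within one spanning tree
#'
#' A spanning tree is balanced by construction, so each node has a unique
#' path to the reference and an unambiguous sign
#' \eqn{s_{n \to REF}(t) \in \{-1, +1\}}: the product of edge signs along
#' that path.
#'
#' @param graph the parent [signed_graph()].
#' @param tree integer vector of edge indices forming a spanning tree of
#'   `graph` (as produced by [enumerate_spanning_trees()]).
#' @return named integer vector of -1/+1 over all nodes.
#' @export
tree_signs <- function(graph, tree) {
  gi <- graph_index(graph)
  if (length(tree) != gi$n - 1L)
    stop("not a spanning tree: expected ", gi$n - 1L, " edges, got ",
         length(tree), call. = FALSE)
  pr <- propagate_signs(gi$n, gi$eu[tree], gi$ev[tree], gi$sign[tree],
                        roots = gi$ref)
  if (anyNA(pr$signs))
    stop("edge set does not span all nodes", call. = FALSE)
  structure(pr$signs, names = graph$nodes)
}

#' Aggregate nodal scores over one spanning tree
#'
#' \eqn{X(t) = \sum_n s_{n \to REF}(t) \, X_n}: the balanced-graph aggregation
#' applied to the tree, which is always well defined.
#'
#' @inheritParams tree_signs
#' @param scores named numeric vector of nodal scores.
#' @param impute_zero treat nodes absent from `scores` as 0.
#' @return scalar \eqn{X(t)}.
#' @export
tree_score <- function(graph, tree, scores, impute_zero = FALSE) {
  x <- node_scores(scores, graph$nodes, impute_zero = impute_zero)
  sum(tree_signs(graph, tree) * x)
}

# internal constructor shared by the exact and sampled paths
new_effective_weights <- function(nodes, n_plus, n_minus, exact) {
  total <- n_plus + n_minus
  S <- (n_plus - n_minus) / total
  se <- if (exact) rep(0, length(nodes)) else sqrt(pmax(0, 1 - S^2) / total)
  structure(list(S = structure(S, names = nodes),
                 n_plus = structure(n_plus, names = nodes),
                 n_minus = structure(n_minus, names = nodes),
                 n_trees = total[[1L]],
                 se = structure(se, names = nodes),
                 exact = exact),
            class = "effective_weights")
}

#' @export
print.effective_weights <- function(x, ...) {
  cat(if (x$exact) "Exact" else "Sampled",
      "effective nodal weights over", format(x$n_trees, big.mark = ","),
      "spanning trees\n")
  tab <- data.frame(S = round(x$S, 4), n_plus = x$n_plus,
                    n_minus = x$n_minus, se = signif(x$se, 3))
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.effective_weights <- function(x, ...) {
  data.frame(node = names(x$S), S = unname(x$S),
             n_plus = unname(x$n_plus), n_minus = unname(x$n_minus),
             se = unname(x$se), stringsAsFactors = FALSE)
}

#' Exact effective nodal weights by full enumeration
#'
#' The effective weight of node \eqn{n} relative to the reference is the
#' average of its path sign over *all* spanning trees,
#' \deqn{S_{n \to REF}(G) = \frac{1}{N(G)} \sum_{i=1}^{N(G)} s_{n \to REF}(t_i)
#' \in [-1, +1],}
#' a structural average that replaces the rigid nodal sign when the graph is
#' unbalanced. Internally the positive and negative tree counts are exact
#' integers, so on a balanced graph the result is bit-exact ±1.
#'
#' @inheritParams enumerate_spanning_trees
#' @return an object of class `"effective_weights"` with elements `S`
#'   (named weights), `n_plus`/`n_minus` (tree-sign counts), `n_trees`,
#'   `se` (0 here) and `exact = TRUE`.
#' @examples
#' exact_effective_weights(iffl())$S   # (A, B, C) = (1, 1/3, 1/3)
#' @export
exact_effective_weights <- function(graph, cap = 1e6) {
  trees <- enumerate_spanning_trees(graph, cap = cap)
  n_plus <- structure(numeric(length(graph$nodes)), names = graph$nodes)
  n_minus <- n_plus
  for (t in trees) {
    s <- tree_signs(graph, t)
    pos <- s > 0
    n_plus[pos] <- n_plus[pos] + 1
    n_minus[!pos] <- n_minus[!pos] + 1
  }
  new_effective_weights(graph$nodes, unname(n_plus), unname(n_minus),
                        exact = TRUE)
}

# balance of a (possibly disconnected) edge subset: no negative cycle in any
# component
balanced_all_components <- function(n, eu, ev, esign) {
  propagate_signs(n, eu, ev, esign, roots = seq_len(n))$balanced
}

#' Line index of balance by brute force
#'
#' The line index of balance `z` is the minimum number of edges whose
#' deletion makes the signed graph balanced; any spanning tree of an
#' unbalanced graph necessarily omits at least `z` edges. This brute-force
#' search over deletion subsets in increasing size is an oracle for small
#' graphs, not a production balancer.
#'
#' @param graph a connected [signed_graph()].
#' @param cap maximum number of deletion subsets examined.
#' @return list with `z` (integer) and `edges`, a data.frame of one witnessing
#'   minimal deletion set (zero rows when already balanced).
#' @examples
#' line_index_of_balance(iffl())$z   # 1
#' @export
line_index_of_balance <- function(graph, cap = 2e5) {
  stop_if_disconnected(graph, "line_index_of_balance")
  gi <- graph_index(graph)
  m <- length(gi$eu)
  examined <- 0
  for (z in 0:m) {
    n_sub <- choose(m, z)
    examined <- examined + n_sub
    if (examined > cap)
      stop("line_index_of_balance: subset search exceeds cap (", cap,
           " subsets); this oracle only supports small graphs", call. = FALSE)
    subsets <- if (z == 0L) matrix(integer(0), nrow = 0)
               else t(utils::combn(m, z))
    if (z == 0L) subsets <- matrix(integer(0), nrow = 1, ncol = 0)
    for (r in seq_len(nrow(subsets))) {
      drop <- subsets[r, ]
      keep <- setdiff(seq_len(m), drop)
      if (balanced_all_components(gi$n, gi$eu[keep], gi$ev[keep],
                                  gi$sign[keep])) {
        witness <- graph$edges[drop, c("source", "target", "sign",
                                       "edge_class"), drop = FALSE]
        rownames(witness) <- NULL
        return(list(z = z, edges = witness))
      }
    }
  }
  stop("unreachable: deleting all edges always balances the graph")
}
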