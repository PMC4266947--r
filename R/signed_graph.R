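#' Construct a signed graph
#'
#' A signed graph is the carrier of a causal network model: nodes joined by
#' edges carrying a sign in \{-1, +1\} (+1, drawn "->", an increase in the
#' source causes an increase in the target; -1, drawn "-|", an increase causes
#' a decrease), plus one designated *reference node* that fixes the absolute
#' sign convention for the whole network. Edge direction is stored for
#' provenance but plays no role in balance, path signs or tree sampling: path
#' signs are defined over non-oriented paths.
#'
#' Self-loops are dropped with a warning (they can never belong to a spanning
#' tree, and a negative self-loop would make any graph trivially unbalanced).
#' Exact duplicate edges (same endpoints, sign and class) are collapsed with a
#' warning; contradictory duplicates (same endpoints, opposite signs) are kept
#' as parallel edges, each an independent traversal choice and a distinct
#' potential tree member.
#'
#' @param edges data.frame with columns `source`, `target`, `sign` (-1 or +1)
#'   and optionally `edge_class` (one of `"intramolecular"`, `"direct"`,
#'   `"indirect"`, `"expression"`, `"default"`).
#' @param reference node identifier of the reference node.
#' @param nodes optional character vector of node identifiers; endpoints and
#'   the reference are added automatically. Use to declare isolated nodes.
#' @return An object of class `"signed_graph"`: a list with elements `nodes`
#'   (character), `edges` (data.frame with `source`, `target`, `sign`,
#'   `edge_class`, `traversal_weight`) and `reference`.
#' @seealso [read_signed_graph()], [check_balance()], [sst()]
#' @examples
#' g <- signed_graph(data.frame(source = c("A", "A", "B"),
#'                              target = c("B", "C", "C"),
#'                              sign   = c(1, 1, -1)),
#'                   reference = "A")
#' g
#' @export
signed_graph <- function(edges, reference, nodes = NULL) {
  if (missing(reference) || length(reference) != 1L || is.na(reference))
    stop("a single reference node must be given", call. = FALSE)
  reference <- as.character(reference)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), edge_class = character(),
                        stringsAsFactors = FALSE)
  }
  if (!all(c("source", "target", "sign") %in% names(edges)))
    stop("`edges` needs columns source, target, sign", call. = FALSE)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 1L)))
    stop("edge signs must be -1 or +1", call. = FALSE)
  if (is.null(edges$edge_class)) edges$edge_class <- rep("default", nrow(edges))
  edges$edge_class <- as.character(edges$edge_class)
  bad_class <- setdiff(unique(edges$edge_class), names(default_class_weights()))
  if (length(bad_class))
    stop("unknown edge class(es): ", paste(bad_class, collapse = ", "),
         call. = FALSE)

  loop <- edges$source == edges$target
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped: self-loops cannot belong to ",
            "a spanning tree", call. = FALSE)
    edges <- edges[!loop, , drop = FALSE]
  }
  key <- paste(edges$source, edges$target, edges$sign, edges$edge_class,
               sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate identical edge(s) collapsed",
            call. = FALSE)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges$traversal_weight <- unname(default_class_weights()[edges$edge_class])

  all_nodes <- unique(c(as.character(nodes), edges$source, edges$target,
                        reference))
  structure(list(nodes = all_nodes, edges = edges, reference = reference),
            class = "signed_graph")
}

#' Default edge-class traversal weights
#'
#' Relative traversal probabilities by edge class, reflecting the semantics of
#' BEL-encoded causal network models: intramolecular edges (a molecule and its
#' activity) are most likely to be retained in a sampled tree, then direct and
#' indirect intermolecular edges, then expression edges, which act on longer
#' timescales and often close feedback loops. Unclassified edges get weight 1.
#'
#' @return named numeric vector of positive weights.
#' @export
default_class_weights <- function() {
  c(intramolecular = 1, direct = 1 / 2, indirect = 1 / 3,
    expression = 1 / 4, default = 1)
}

#' @export
print.signed_graph <- function(x, ...) {
  m <- nrow(x$edges)
  cat("Signed graph: ", length(x$nodes), " nodes, ", m, " edges (",
      sum(x$edges$sign < 0), " negative), reference node '", x$reference,
      "'\n", sep = "")
  invisible(x)
}

# integer endpoint representation used by all internal algorithms
graph_index <- function(graph) {
  list(n = length(graph$nodes),
       eu = match(graph$edges$source, graph$nodes),
       ev = match(graph$edges$target, graph$nodes),
       sign = graph$edges$sign,
       ref = match(graph$reference, graph$nodes))
}

# connected components by BFS over the non-oriented edge set; returns a
# component label per node
node_components <- function(n, eu, ev) {
  adj <- vector("list", n)
  for (k in seq_along(eu)) {
    adj[[eu[k]]] <- c(adj[[eu[k]]], ev[k])
    adj[[ev[k]]] <- c(adj[[ev[k]]], eu[k])
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Is a signed graph connected?
#'
#' @param graph a [signed_graph()].
#' @return logical.
#' @export
is_connected <- function(graph) {
  gi <- graph_index(graph)
  all(node_components(gi$n, gi$eu, gi$ev) == 1L)
}

stop_if_disconnected <- function(graph, what) {
  if (!is_connected(graph))
    stop(what, " requires a connected graph: balance and tree sampling are ",
         "ambiguous with respect to a single reference node on a ",
         "disconnected graph. Consider reference_component().", call. = FALSE)
  invisible(graph)
}

#' Extract the connected component containing the reference node
#'
#' Convenience for inputs whose other components are irrelevant to
#' aggregation against the reference.
#'
#' @param graph a [signed_graph()].
#' @return a connected [signed_graph()] on the reference's component.
#' @export
reference_component <- function(graph) {
  gi <- graph_index(graph)
  comp <- node_components(gi$n, gi$eu, gi$ev)
  keep_nodes <- graph$nodes[comp == comp[gi$ref]]
  keep <- graph$edges$source %in% keep_nodes & graph$edges$target %in% keep_nodes
  signed_graph(graph$edges[keep, c("source", "target", "sign", "edge_class")],
               reference = graph$reference, nodes = keep_nodes)
}

# sign propagation over an arbitrary (multi)edge set given by integer
# endpoints; used by check_balance and by line_index_of_balance (which allows
# disconnected remainders). Returns list(balanced, signs, conflict_edge,
# parent_edge) where signs are per-node +-1 within each reached component.
propagate_signs <- function(n, eu, ev, esign, roots) {
  adj_edge <- vector("list", n)
  for (k in seq_along(eu)) {
    adj_edge[[eu[k]]] <- c(adj_edge[[eu[k]]], k)
    adj_edge[[ev[k]]] <- c(adj_edge[[ev[k]]], k)
  }
  signs <- rep(NA_integer_, n)
  parent_edge <- rep(NA_integer_, n)
  for (root in roots) {
    if (!is.na(signs[root])) next
    signs[root] <- 1L
    queue <- root
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (k in adj_edge[[v]]) {
        w <- if (eu[k] == v) ev[k] else eu[k]
        s <- signs[v] * esign[k]
        if (is.na(signs[w])) {
          signs[w] <- s
          parent_edge[w] <- k
          queue <- c(queue, w)
        } else if (signs[w] != s) {
          return(list(balanced = FALSE, signs = signs,
                      conflict_edge = k, parent_edge = parent_edge))
        }
      }
    }
  }
  list(balanced = TRUE, signs = signs, conflict_edge = NA_integer_,
       parent_edge = parent_edge)
}

# path of BFS-tree edge indices from node v up to its root
tree_path_edges <- function(v, parent_edge, eu, ev) {
  path <- integer(0)
  while (!is.na(parent_edge[v])) {
    k <- parent_edge[v]
    path <- c(path, k)
    v <- if (eu[k] == v) ev[k] else eu[k]
  }
  path
}

#' Check balance (causal consistency) of a signed graph
#'
#' A connected signed graph is *balanced* when the relative sign between every
#' node pair is path-independent, equivalently when every cycle has positive
#' edge-sign product. Balanced graphs are exactly the causally consistent
#' network models on which sign-weighted aggregation ([aggregate_balanced()])
#' is defined; unbalanced graphs require the spanning-tree relaxation
#' ([sst()]).
#'
#' Signs are propagated from the reference node by breadth-first search. On a
#' balanced graph the propagated signs are the nodal signs
#' \eqn{s_{n \to REF}(G)}. On an unbalanced graph one negative cycle is
#' returned as a witness: the first contradicting edge together with the two
#' propagation paths back to their common ancestor.
#'
#' @param graph a connected [signed_graph()].
#' @return A list of class `"balance_report"`: `balanced` (logical);
#'   `node_signs` (named vector of -1/+1, only if balanced);
#'   `witness_cycle` (data.frame of edges whose sign product is -1, only if
#'   unbalanced).
#' @examples
#' check_balance(iffl())             # unbalanced: the incoherent loop
#' @export
check_balance <- function(graph) {
  stop_if_disconnected(graph, "check_balance")
  gi <- graph_index(graph)
  if (gi$n == 1L) {
    signs <- structure(1L, names = graph$nodes)
    return(structure(list(balanced = TRUE, node_signs = signs,
                          witness_cycle = NULL), class = "balance_report"))
  }
  pr <- propagate_signs(gi$n, gi$eu, gi$ev, gi$sign, gi$ref)
  if (pr$balanced) {
    signs <- structure(pr$signs, names = graph$nodes)
    return(structure(list(balanced = TRUE, node_signs = signs,
                          witness_cycle = NULL), class = "balance_report"))
  }
  k <- pr$conflict_edge
  pu <- tree_path_edges(gi$eu[k], pr$parent_edge, gi$eu, gi$ev)
  pv <- tree_path_edges(gi$ev[k], pr$parent_edge, gi$eu, gi$ev)
  cyc <- c(k, setdiff(union(pu, pv), intersect(pu, pv)))
  witness <- graph$edges[cyc, c("source", "target", "sign", "edge_class")]
  rownames(witness) <- NULL
  stopifnot(prod(witness$sign) == -1L)
  structure(list(balanced = FALSE, node_signs = NULL,
                 witness_cycle = witness), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  if (x$balanced) {
    cat("Balanced (causally consistent) signed graph.\n")
    cat("Nodal signs relative to the reference:\n")
    print(x$node_signs)
  } else {
    cat("Unbalanced (causally inconsistent) signed graph.\n")
    cat("Witness negative cycle (edge-sign product -1):\n")
    print(x$witness_cycle)
  }
  invisible(x)
}

#' Sign-weighted aggregation on a balanced graph
#'
#' On a connected balanced graph the aggregate of nodal scores is
#' \eqn{X_G = \sum_n s_{n \to REF}(G) \, X_n}, with nodal signs obtained by
#' propagating edge signs from the reference node (path-independent precisely
#' because the graph is balanced).
#'
#' @param graph a connected, balanced [signed_graph()].
#' @param scores named numeric vector of nodal scores \eqn{X_n} covering all
#'   nodes (see [node_scores()]).
#' @param impute_zero if `TRUE`, nodes missing from `scores` contribute 0;
#'   by default a missing score is an error.
#' @return the scalar aggregate \eqn{X_G}.
#' @examples
#' g <- signed_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
#'                              sign = c(1, -1)), reference = "A")
#' aggregate_balanced(g, c(A = 1, B = 1, C = 1))   # 1 + 1 - 1 = 1
#' @export
aggregate_balanced <- function(graph, scores, impute_zero = FALSE) {
  rep <- check_balance(graph)
  if (!rep$balanced)
    stop("graph is unbalanced: nodal signs are path-dependent; use sst() ",
         "to aggregate via spanning-tree effective weights", call. = FALSE)
  x <- node_scores(scores, graph$nodes, impute_zero = impute_zero)
  sum(rep$node_signs * x)
}

#' Validate nodal scores against a node set
#'
#' @param scores named numeric vector mapping node identifiers to real scores.
#' @param nodes character vector of graph nodes the scores must cover.
#' @param impute_zero if `TRUE`, absent nodes get score 0 (a node with no
#'   measurement contributes nothing); otherwise absence is an error.
#' @return numeric vector ordered as `nodes`.
#' @export
node_scores <- function(scores, nodes, impute_zero = FALSE) {
  if (is.null(names(scores)))
    stop("scores must be a named numeric vector (node -> value)",
         call. = FALSE)
  if (!all(is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  extra <- setdiff(names(scores), nodes)
  if (length(extra))
    stop("scores given for unknown node(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(nodes, names(scores))
  if (length(missing) && !impute_zero)
    stop("no score for node(s): ", paste(missing, collapse = ", "),
         "; pass impute_zero = TRUE to treat them as 0", call. = FALSE)
  out <- structure(numeric(length(nodes)), names = nodes)
  out[names(scores)] <- as.numeric(scores)
  out
}
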