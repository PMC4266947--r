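#' Aggregate nodal scores with effective weights
#'
#' \deqn{X_G = \sum_n S_{n \to REF}(G) \, X_n,} the continuous generalisation
#' of the balanced-graph aggregation: on a balanced graph the effective
#' weights are exactly the propagated nodal signs and the two coincide; on an
#' unbalanced graph the weights average the path signs over spanning trees.
#' Works identically with exact and sampled weights.
#'
#' @param weights an `"effective_weights"` object, from
#'   [exact_effective_weights()] or [estimate_effective_weights()].
#' @param scores named numeric vector of nodal scores.
#' @param impute_zero treat nodes absent from `scores` as 0.
#' @return the scalar aggregate \eqn{X_G}.
#' @examples
#' aggregate_scores(exact_effective_weights(iffl()),
#'                  c(A = 1, B = 1, C = 1))     # 5/3
#' @export
aggregate_scores <- function(weights, scores, impute_zero = FALSE) {
  stopifnot(inherits(weights, "effective_weights"))
  x <- node_scores(scores, names(weights$S), impute_zero = impute_zero)
  sum(weights$S * x)
}

#' Per-tree score distribution and the most representative tree
#'
#' Computes the aggregated score \eqn{X(t)} of each spanning tree in a
#' collection (enumerated or sampled), the overall aggregate as their mean,
#' and the *most representative spanning tree* \eqn{t^*}: the tree whose
#' score is closest to the aggregate, \eqn{\arg\min_t |X(t) - X_G|} (ties
#' broken by the first tree in collection order). Because a spanning tree
#' fixes an unambiguous sign for every node, \eqn{t^*} extends to a balanced
#' subgraph \eqn{G^*}: \eqn{t^*} plus every non-tree edge of the graph whose
#' endpoint signs under \eqn{t^*} are consistent with its edge sign, i.e. the
#' maximal balanced subgraph of the graph containing \eqn{t^*}.
#'
#' @param graph the parent [signed_graph()].
#' @param trees list of spanning trees (integer edge-index vectors), e.g.
#'   from [enumerate_spanning_trees()] or [sample_spanning_trees()]`$trees`.
#' @param scores named numeric vector of nodal scores.
#' @param impute_zero treat nodes absent from `scores` as 0.
#' @return list with `x_g` (mean of per-tree scores), `per_tree_scores`,
#'   `representative_tree` (edge indices of \eqn{t^*}),
#'   `representative_index` (its position in `trees`) and
#'   `representative_subgraph_edges` (edge indices of \eqn{G^*}).
#' @examples
#' g <- iffl()
#' per_tree_distribution(g, enumerate_spanning_trees(g),
#'                       c(A = 1, B = 1, C = 1))
#' @export
per_tree_distribution <- function(graph, trees, scores, impute_zero = FALSE) {
  if (!length(trees)) stop("empty tree collection", call. = FALSE)
  x <- node_scores(scores, graph$nodes, impute_zero = impute_zero)
  sign_list <- lapply(trees, function(t) tree_signs(graph, t))
  per_tree <- vapply(sign_list, function(s) sum(s * x), numeric(1))
  x_g <- mean(per_tree)
  i_star <- which.min(abs(per_tree - x_g))
  t_star <- trees[[i_star]]
  s_star <- sign_list[[i_star]]
  gi <- graph_index(graph)
  consistent <- s_star[gi$eu] * s_star[gi$ev] == gi$sign
  g_star <- sort(union(t_star, which(consistent)))
  list(x_g = x_g, per_tree_scores = per_tree,
       representative_tree = t_star, representative_index = i_star,
       representative_subgraph_edges = g_star)
}

#' Compare effective weights with reference nodal signs
#'
#' Treats the continuous effective weights as predictions of reference sign
#' assignments \eqn{s_{n \to REF} \in \{-1, +1\}} (for example the nodal
#' signs of a manually pruned, causally consistent version of the network)
#' and scores them as a classifier. The mislabeling rate uses a zero
#' threshold, with an exactly-zero weight counted as mislabeled (it carries
#' no direction). The ROC curve sweeps the decision threshold over the
#' distinct weight values with \eqn{s = +1} as the positive class; AUROC is
#' its trapezoid integral, and is `NA` when only one class is present.
#'
#' @param weights an `"effective_weights"` object, or a named numeric vector
#'   of weights in \[-1, 1\].
#' @param reference_signs named vector of -1/+1 over the same nodes.
#' @return list of class `"sst_comparison"`: `mislabel_rate`, `roc_points`
#'   (data.frame `fpr`, `tpr`), `auroc`, and `per_node` (node, S, s, agree).
#' @export
compare_to_reference_signs <- function(weights, reference_signs) {
  S <- if (inherits(weights, "effective_weights")) weights$S else weights
  if (is.null(names(S)) || is.null(names(reference_signs)))
    stop("weights and reference_signs must be named by node", call. = FALSE)
  if (!setequal(names(S), names(reference_signs)))
    stop("weights and reference_signs must cover the same node set",
         call. = FALSE)
  s <- reference_signs[names(S)]
  if (!all(s %in% c(-1, 1)))
    stop("reference signs must be -1 or +1", call. = FALSE)

  agree <- (S > 0 & s > 0) | (S < 0 & s < 0)   # S == 0 counts as mislabeled
  mislabel_rate <- mean(!agree)

  pos <- s > 0
  n_pos <- sum(pos); n_neg <- sum(!pos)
  thresholds <- c(Inf, sort(unique(unname(S)), decreasing = TRUE))
  roc <- t(vapply(thresholds, function(th) {
    pred <- S >= th
    c(fpr = if (n_neg) sum(pred & !pos) / n_neg else NA_real_,
      tpr = if (n_pos) sum(pred & pos) / n_pos else NA_real_)
  }, numeric(2)))
  roc_points <- data.frame(threshold = thresholds, fpr = roc[, "fpr"],
                           tpr = roc[, "tpr"])
  auroc <- if (n_pos == 0 || n_neg == 0) NA_real_ else
    sum(diff(roc_points$fpr) *
          (utils::head(roc_points$tpr, -1) + utils::tail(roc_points$tpr, -1)) / 2)
  structure(list(mislabel_rate = mislabel_rate, roc_points = roc_points,
                 auroc = auroc,
                 per_node = data.frame(node = names(S), S = unname(S),
                                       s = unname(s), agree = unname(agree),
                                       stringsAsFactors = FALSE)),
            class = "sst_comparison")
}

#' @export
print.sst_comparison <- function(x, ...) {
  cat("Effective weights vs reference signs over", nrow(x$per_node),
      "nodes\n")
  cat("  mislabel rate (zero threshold):",
      sprintf("%.1f%%", 100 * x$mislabel_rate), "\n")
  cat("  AUROC:", if (is.na(x$auroc)) "undefined (single class)" else
    sprintf("%.3f", x$auroc), "\n")
  invisible(x)
}
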