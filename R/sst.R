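#' Fit effective nodal weights and aggregate scores over a signed graph
#'
#' The main entry point. Given a connected signed graph with a reference
#' node, `sst()` determines the effective nodal weights
#' \eqn{S_{n \to REF}(G) \in [-1, +1]} — the average of each node's path sign
#' over the graph's spanning trees — and, when nodal scores are supplied,
#' the aggregate \eqn{X_G = \sum_n S_n X_n} together with the per-tree score
#' distribution and the most representative spanning tree.
#'
#' Methods:
#' * `"sampling"` — Monte-Carlo estimation from `n_trees` signed random
#'   walkers (Aldous' first-entrance spanning-tree sampling); scales to
#'   arbitrary graphs.
#' * `"exact"` — full contraction-deletion enumeration of the spanning trees;
#'   only for graphs with at most `cap` trees.
#' * `"auto"` — balanced graphs are solved exactly by sign propagation (the
#'   weights are then rigid signs, no sampling variance); unbalanced graphs
#'   fall through to `"sampling"`.
#'
#' @param graph a connected [signed_graph()].
#' @param scores optional named numeric vector of nodal scores \eqn{X_n}.
#' @param method `"auto"`, `"sampling"` or `"exact"` (see Details).
#' @param n_trees number of sampled spanning trees (sampling method).
#' @param seed integer seed for the walker streams.
#' @param profile traversal-weight profile, see [traversal_weights()].
#' @param edge_class_weights optional class-weight override.
#' @param cap enumeration cap for `method = "exact"`.
#' @param keep_trees keep the individual sampled/enumerated trees (needed for
#'   the per-tree distribution and \eqn{t^*}; default on when `scores` are
#'   given).
#' @param impute_zero treat nodes absent from `scores` as 0.
#' @param max_steps per-walker step budget, see
#'   [estimate_effective_weights()].
#' @return An object of class `"sst"`: list with `weights`
#'   (`"effective_weights"`), `method` (`"balanced-exact"`,
#'   `"enumeration-exact"` or `"sst-sampled"`), `graph`, `balance`
#'   (the [check_balance()] report), and when scores were given `scores`,
#'   `x_g`, `per_tree` (the [per_tree_distribution()] result, if trees were
#'   kept). Supports [coef()], [print()], [summary()], [plot()] and
#'   [predict()].
#' @examples
#' fit <- sst(iffl(), scores = c(A = 1, B = 1, C = 1), method = "exact")
#' fit
#' coef(fit)               # (1, 1/3, 1/3)
#' fit$x_g                 # 5/3
#' predict(fit, c(A = 1, B = 2, C = 0))
#' @export
sst <- function(graph, scores = NULL,
                method = c("auto", "sampling", "exact"),
                n_trees = 1000, seed = 1L,
                profile = c("uniform", "bel"), edge_class_weights = NULL,
                cap = 1e6, keep_trees = !is.null(scores),
                impute_zero = FALSE, max_steps = NULL) {
  stopifnot(inherits(graph, "signed_graph"))
  method <- match.arg(method)
  profile <- match.arg(profile)
  stop_if_disconnected(graph, "sst")
  balance <- check_balance(graph)

  trees <- NULL
  if (method == "auto" && balance$balanced) {
    s <- balance$node_signs
    weights <- new_effective_weights(graph$nodes,
                                     n_plus = as.numeric(s > 0),
                                     n_minus = as.numeric(s < 0),
                                     exact = TRUE)
    method_used <- "balanced-exact"
    if (keep_trees) trees <- enumerate_spanning_trees(graph, cap = cap)
  } else if (method == "exact") {
    trees <- enumerate_spanning_trees(graph, cap = cap)
    weights <- exact_effective_weights(graph, cap = cap)
    method_used <- "enumeration-exact"
  } else {
    if (keep_trees) {
      sam <- sample_spanning_trees(graph, n_trees = n_trees, seed = seed,
                                   profile = profile,
                                   edge_class_weights = edge_class_weights,
                                   max_steps = max_steps)
      weights <- sam$weights
      trees <- sam$trees
    } else {
      weights <- estimate_effective_weights(graph, n_trees = n_trees,
                                            seed = seed, profile = profile,
                                            edge_class_weights =
                                              edge_class_weights,
                                            max_steps = max_steps)
    }
    method_used <- "sst-sampled"
  }

  fit <- structure(list(weights = weights, method = method_used,
                        graph = graph, balance = balance, trees = trees,
                        n_trees = weights$n_trees, seed = seed,
                        profile = profile, call = match.call()),
                   class = "sst")
  if (!is.null(scores)) {
    fit$scores <- scores
    fit$x_g <- aggregate_scores(weights, scores, impute_zero = impute_zero)
    if (!is.null(trees))
      fit$per_tree <- per_tree_distribution(graph, trees, scores,
                                            impute_zero = impute_zero)
  }
  fit
}

#' @export
coef.sst <- function(object, ...) object$weights$S

#' @export
print.sst <- function(x, ...) {
  cat("Spanning-tree score aggregation (", x$method, ")\n", sep = "")
  print(x$graph)
  cat("Graph is ", if (x$balance$balanced) "balanced" else "unbalanced",
      "; effective weights from ",
      format(x$n_trees, big.mark = ","), " spanning tree(s)\n", sep = "")
  if (!is.null(x$x_g))
    cat("Aggregate X_G =", format(x$x_g, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.sst <- function(object, ...) {
  tab <- as.data.frame(object$weights)
  per_tree <- NULL
  if (!is.null(object$per_tree)) {
    s <- object$per_tree$per_tree_scores
    per_tree <- c(mean = mean(s), sd = stats::sd(s), min = min(s),
                  max = max(s))
  }
  structure(list(fit = object, table = tab, per_tree_summary = per_tree),
            class = "summary.sst")
}

#' @export
print.summary.sst <- function(x, ...) {
  print(x$fit)
  cat("\nEffective nodal weights:\n")
  print(x$table, digits = 4)
  if (!is.null(x$per_tree_summary)) {
    cat("\nPer-tree score distribution:\n")
    print(round(x$per_tree_summary, 4))
    cat("Most representative tree: #", x$fit$per_tree$representative_index,
        " (", length(x$fit$per_tree$representative_subgraph_edges),
        " of ", nrow(x$fit$graph$edges),
        " edges sign-consistent with it)\n", sep = "")
  }
  invisible(x)
}

#' Aggregate new nodal scores with a fitted weight set
#'
#' @param object an [sst()] fit.
#' @param newscores named numeric vector of nodal scores; defaults to the
#'   scores used at fit time.
#' @param impute_zero treat nodes absent from `newscores` as 0.
#' @param ... unused.
#' @return the scalar aggregate \eqn{X_G} under `object`'s weights.
#' @export
predict.sst <- function(object, newscores = object$scores,
                        impute_zero = FALSE, ...) {
  if (is.null(newscores))
    stop("no scores: supply `newscores`", call. = FALSE)
  aggregate_scores(object$weights, newscores, impute_zero = impute_zero)
}

#' Plot effective nodal weights
#'
#' Dot plot of the fitted weights in \[-1, 1\] with ±2 SE bars (sampled
#' fits), nodes ordered by weight.
#'
#' @param x an [sst()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sst <- function(x, ...) {
  S <- sort(x$weights$S)
  se <- x$weights$se[names(S)]
  idx <- seq_along(S)
  graphics::plot(S, idx, xlim = c(-1.05, 1.05), yaxt = "n", pch = 19,
                 xlab = expression(S[n %->% REF]), ylab = "",
                 panel.first = graphics::abline(v = 0, col = "grey70",
                                                lty = 2), ...)
  graphics::axis(2, at = idx, labels = names(S), las = 1, cex.axis = 0.7)
  graphics::segments(pmax(-1, S - 2 * se), idx, pmin(1, S + 2 * se), idx)
  invisible(x)
}
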