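#' The incoherent feed-forward loop
#'
#' The minimal unbalanced (causally inconsistent) motif: A activates B and C,
#' while B inhibits C. The two non-oriented paths between A and B (direct,
#' and through C) disagree in sign, so no consistent nodal signs exist. Its
#' three spanning trees yield exact effective weights
#' \eqn{(S_A, S_B, S_C) = (1, 1/3, 1/3)} relative to reference A.
#'
#' @return a [signed_graph()] with nodes A, B, C and reference A.
#' @examples
#' check_balance(iffl())$balanced            # FALSE
#' exact_effective_weights(iffl())$S         # 1, 1/3, 1/3
#' @export
iffl <- function() {
  signed_graph(data.frame(source = c("A", "A", "B"),
                          target = c("B", "C", "C"),
                          sign = c(1L, 1L, -1L),
                          stringsAsFactors = FALSE),
               reference = "A")
}

# run code under a private, seeded RNG state, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# uniform random labelled tree on n nodes via a random Pruefer sequence
random_tree_edges <- function(n) {
  if (n == 1L) return(cbind(integer(0), integer(0)))
  if (n == 2L) return(cbind(1L, 2L))
  pruefer <- sample.int(n, n - 2L, replace = TRUE)
  degree <- rep(1L, n)
  for (p in pruefer) degree[p] <- degree[p] + 1L
  eu <- ev <- integer(n - 1L)
  ptr <- 0L
  for (i in seq_len(n - 2L)) {
    leaf <- which(degree == 1L)[1L]
    ptr <- ptr + 1L
    eu[ptr] <- leaf; ev[ptr] <- pruefer[i]
    degree[leaf] <- 0L
    degree[pruefer[i]] <- degree[pruefer[i]] - 1L
  }
  last <- which(degree == 1L)
  eu[n - 1L] <- last[1L]; ev[n - 1L] <- last[2L]
  cbind(eu, ev)
}

#' Generate a random connected signed graph
#'
#' Builds a uniform random labelled spanning-tree backbone (connectivity by
#' construction at any density), then adds the remaining edges uniformly at
#' random among node pairs not yet joined, so the generated graph is simple.
#' Signs are i.i.d. negative with probability `p_negative`; edge classes are
#' drawn from `class_mix`. With `force_unbalanced = TRUE` the edge signs are
#' resampled (bounded retries) until the graph is unbalanced; this is
#' impossible for trees, which are always balanced.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param n_edges number of edges (>= `n_nodes - 1`, <= `choose(n_nodes, 2)`).
#' @param p_negative probability that an edge has sign -1.
#' @param class_mix named vector of edge-class fractions summing to 1;
#'   default all `"default"` (uniform traversal).
#' @param force_unbalanced resample signs until the graph is unbalanced.
#' @param seed integer seed; generation is deterministic given the spec.
#' @param reference reference node index (default 1, node `"n001"`).
#' @return a connected [signed_graph()].
#' @examples
#' g <- random_signed_graph(20, 30, p_negative = 0.2, seed = 7,
#'                          force_unbalanced = TRUE)
#' check_balance(g)$balanced    # FALSE
#' @export
random_signed_graph <- function(n_nodes, n_edges = n_nodes - 1L,
                                p_negative = 0.2,
                                class_mix = c(default = 1),
                                force_unbalanced = FALSE, seed = 1L,
                                reference = 1L) {
  stopifnot(n_nodes >= 1, n_edges >= n_nodes - 1L,
            n_edges <= choose(n_nodes, 2),
            p_negative >= 0, p_negative <= 1)
  if (abs(sum(class_mix) - 1) > 1e-8 || is.null(names(class_mix)))
    stop("class_mix must be a named vector of fractions summing to 1",
         call. = FALSE)
  if (force_unbalanced && n_edges == n_nodes - 1L)
    stop("cannot force an unbalanced graph with n_edges = n_nodes - 1: ",
         "trees are always balanced", call. = FALSE)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  with_local_seed(seed, {
    ends <- random_tree_edges(n_nodes)
    n_extra <- n_edges - (n_nodes - 1L)
    if (n_extra > 0L) {
      # pairs not already joined by the backbone, uniform without replacement
      pair_id <- function(a, b) (pmin(a, b) - 1) * n_nodes + pmax(a, b)
      all_pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)),
                         arr.ind = TRUE)
      used <- pair_id(ends[, 1L], ends[, 2L])
      free <- pair_id(all_pairs[, 1L], all_pairs[, 2L])
      keep <- !(free %in% used)
      pick <- which(keep)[sample.int(sum(keep), n_extra)]
      ends <- rbind(ends, cbind(all_pairs[pick, 1L], all_pairs[pick, 2L]))
    }
    m <- nrow(ends)
    classes <- sample(names(class_mix), m, replace = TRUE, prob = class_mix)
    draw_signs <- function()
      ifelse(stats::runif(m) < p_negative, -1L, 1L)
    make <- function(signs)
      signed_graph(data.frame(source = nodes[ends[, 1L]],
                              target = nodes[ends[, 2L]],
                              sign = signs, edge_class = classes,
                              stringsAsFactors = FALSE),
                   reference = nodes[reference], nodes = nodes)
    g <- make(draw_signs())
    if (force_unbalanced) {
      tries <- 1L
      while (check_balance(g)$balanced) {
        if (tries >= 100L)
          stop("could not obtain an unbalanced graph in 100 sign resamples; ",
               "increase n_edges or p_negative", call. = FALSE)
        g <- make(draw_signs())
        tries <- tries + 1L
      }
    }
    g
  })
}

#' Generate random nodal scores
#'
#' `"unit"` sets every score to 1 (the typical-differential-expression
#' convention used in worked examples); `"gaussian"` draws i.i.d. normal
#' scores. Deterministic for a fixed seed.
#'
#' @param nodes character vector of node identifiers (or a [signed_graph()]).
#' @param distribution `"unit"` or `"gaussian"`.
#' @param mean,sd parameters of the gaussian.
#' @param seed integer seed.
#' @return named numeric vector over `nodes`.
#' @export
random_scores <- function(nodes, distribution = c("unit", "gaussian"),
                          mean = 0, sd = 1, seed = 1L) {
  if (inherits(nodes, "signed_graph")) nodes <- nodes$nodes
  if (!length(nodes)) stop("empty node set", call. = FALSE)
  distribution <- match.arg(distribution)
  x <- switch(distribution,
              unit = rep(1, length(nodes)),
              gaussian = with_local_seed(seed,
                stats::rnorm(length(nodes), mean = mean, sd = sd)))
  structure(x, names = nodes)
}
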