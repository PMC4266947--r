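#' Read a signed graph from an edge-list file
#'
#' The default dialect is tab- (or whitespace-) separated records
#' `source  relation  target  [class]`, one edge per line. Relation tokens
#' `->` and `increases` map to sign +1, `-|` and `decreases` to -1; the
#' `"sif"` dialect additionally accepts `activates`/`inhibits`. Lines starting
#' with `#` are comments, except the directives `#ref <node>` (declares the
#' reference node) and `#node <node>` (declares a node with no edges). The
#' optional fourth column is the edge class (see [default_class_weights()]).
#'
#' @param path file to read.
#' @param reference reference node; overrides any `#ref` directive. One of the
#'   two must be present.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @return a [signed_graph()].
#' @export
read_signed_graph <- function(path, reference = NULL,
                              dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  relmap <- c("->" = 1L, "increases" = 1L, "-|" = -1L, "decreases" = -1L)
  if (dialect == "sif")
    relmap <- c(relmap, "activates" = 1L, "inhibits" = -1L)

  lines <- readLines(path, warn = FALSE)
  declared_nodes <- character(0)
  file_ref <- NULL
  src <- tgt <- cls <- character(0)
  sgn <- integer(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      tok <- strsplit(sub("^#", "", line), "[ \t]+")[[1]]
      tok <- tok[nzchar(tok)]
      if (length(tok) >= 2 && tok[1] == "ref") file_ref <- tok[2]
      if (length(tok) >= 2 && tok[1] == "node")
        declared_nodes <- c(declared_nodes, tok[2])
      next
    }
    tok <- strsplit(line, "[ \t]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) < 3)
      stop("line ", i, ": expected 'source relation target [class]', got: ",
           line, call. = FALSE)
    if (!tok[2] %in% names(relmap))
      stop("line ", i, ": unknown relation token '", tok[2], "' (expected ",
           paste(names(relmap), collapse = ", "), ")", call. = FALSE)
    src <- c(src, tok[1]); tgt <- c(tgt, tok[3])
    sgn <- c(sgn, relmap[[tok[2]]])
    cls <- c(cls, if (length(tok) >= 4) tok[4] else "default")
  }
  reference <- reference %||% file_ref
  if (is.null(reference))
    stop("no reference node: pass `reference` or add a '#ref <node>' ",
         "directive to the file", call. = FALSE)
  signed_graph(data.frame(source = src, target = tgt, sign = sgn,
                          edge_class = cls, stringsAsFactors = FALSE),
               reference = reference, nodes = declared_nodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a signed graph to the edge-list format
#'
#' Emits the `#ref` directive, `#node` directives for isolated nodes, and one
#' `source relation target class` record per edge, readable back by
#' [read_signed_graph()].
#'
#' @param graph a [signed_graph()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_signed_graph <- function(graph, path) {
  e <- graph$edges
  rel <- ifelse(e$sign > 0, "->", "-|")
  isolated <- setdiff(graph$nodes, c(e$source, e$target, graph$reference))
  lines <- c(paste0("#ref\t", graph$reference),
             if (length(isolated)) paste0("#node\t", isolated),
             if (nrow(e)) paste(e$source, rel, e$target, e$edge_class,
                                sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read nodal scores from a two-column file
#'
#' Format: `node<TAB>score`, optional header line (detected when the second
#' field is not numeric).
#'
#' @param path file to read.
#' @return named numeric vector.
#' @export
read_node_scores <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("node", "score"),
                           colClasses = c("character", "character"))
  if (nrow(tab) && is.na(suppressWarnings(as.numeric(tab$score[1]))))
    tab <- tab[-1, , drop = FALSE]
  val <- suppressWarnings(as.numeric(tab$score))
  if (anyNA(val))
    stop("non-numeric score value(s) in ", path, call. = FALSE)
  structure(val, names = tab$node)
}
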