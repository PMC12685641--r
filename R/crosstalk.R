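# Pathway crosstalk scoring: a node's crosstalk score is its total degree
# minus its degree within its own pathway(s), on the undirected simple
# view. Nodes with a positive score bridge distinct pathways.

#' Crosstalk scores
#'
#' `score(v) = deg_total(v) - deg_within(v)`, where by default a neighbor
#' counts as "within" when it shares at least one pathway label with `v`
#' (`mode = "any"`). The stricter alternative `mode = "all"` requires all
#' of the neighbor's labels to be shared. Nodes with score > 0 are
#' crosstalk points.
#'
#' @param network An `interaction_network`.
#' @param annotation Named list mapping node id to a character vector of
#'   pathway names; must cover every node with degree > 0.
#' @param mode `"any"` (default) or `"all"`.
#' @return Named integer vector of scores, one per node.
#' @export
crosstalk_scores <- function(network, annotation, mode = c("any", "all")) {
  mode <- match.arg(mode)
  u <- network$ugraph
  deg <- igraph::degree(u)
  active <- names(deg)[deg > 0]
  missing <- setdiff(active, names(annotation))
  if (length(missing)) {
    stop("unannotated non-isolated node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  shares <- function(a, b) {
    if (mode == "any") length(intersect(a, b)) > 0 else all(b %in% a)
  }
  out <- stats::setNames(integer(igraph::vcount(u)), igraph::V(u)$name)
  for (v in names(out)) {
    nb <- igraph::neighbors(u, v)$name
    if (length(nb) == 0) next
    within <- sum(vapply(nb, function(w) {
      shares(annotation[[v]], annotation[[w]])
    }, TRUE))
    out[v] <- length(nb) - within
  }
  out
}

#' Crosstalk points
#'
#' @param network An `interaction_network`.
#' @param annotation Pathway annotation (see [crosstalk_scores()]).
#' @param mode Sharing mode, forwarded.
#' @return Character vector of nodes with positive crosstalk score,
#'   ordered by decreasing score then id.
#' @export
crosstalk_points <- function(network, annotation, mode = "any") {
  sc <- crosstalk_scores(network, annotation, mode = mode)
  pos <- sc[sc > 0]
  names(pos)[order(-pos, names(pos))]
}

#' Read/write pathway annotations as two-column tables
#'
#' The on-disk format is a CSV with columns `node`, `pathway`; nodes with
#' several memberships occupy several rows.
#'
#' @param path File path.
#' @param annotation Named list node -> pathways.
#' @return `read_annotation()` returns the named list form.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df$pathway, df$node)
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(
    node = rep(names(annotation), lengths(annotation)),
    pathway = unlist(annotation, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.csv(df[order(df$node, df$pathway), ], path,
                   row.names = FALSE)
  invisible(path)
}
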