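# Species interaction network derived from a kinetic model, its topology
# summary, the twelve CytoHubba-style node centralities, and the
# hub frequency-of-occurrence report.

CENTRALITY_METRICS <- c("degree", "closeness", "betweenness", "bottleneck",
                        "clustering_coefficient", "mnc", "dmnc",
                        "eccentricity", "epc", "mcc", "radiality", "stress")

#' Derive the species interaction network of a model
#'
#' For every reaction, a directed edge is drawn from each reactant and
#' modifier (source) to each product (target). Species appearing on both
#' sides of a reaction — gene templates and catalytic complexes — are
#' conserved, so they act as sources only and no self-loops arise.
#' Gene-expression (Hill) reactions follow the transcription convention:
#' the transcription factor points at the gene locus it binds and the
#' locus at its transcript (TF -> gene -> product), mirroring the physical
#' order of events. Parallel duplicate edges are collapsed; nodes are
#' ordered lexicographically by id.
#'
#' @param model A `reaction_model`.
#' @return An `interaction_network`: list with the directed [igraph] graph
#'   (`graph`), the undirected simple view (`ugraph`) on which centralities
#'   are computed, and the node table.
#' @export
model_to_network <- function(model) {
  edges <- matrix(character(), ncol = 2)
  for (rx in model$reactions) {
    sources <- union(names(rx$reactants), rx$modifiers)
    targets <- setdiff(names(rx$products), sources)
    if (rx$rate$kind == "hill" && length(rx$modifiers) == 1) {
      gene <- intersect(names(rx$reactants), names(rx$products))
      if (length(gene) == 1 && length(targets)) {
        edges <- rbind(edges, cbind(rx$modifiers, gene),
                       cbind(gene, targets))
        next
      }
    }
    if (length(sources) && length(targets)) {
      edges <- rbind(edges, as.matrix(expand.grid(
        source = sources, target = targets,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
    }
  }
  edges <- unique(edges)
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  structure(list(
    graph = g,
    ugraph = igraph::as_undirected(igraph::simplify(g), mode = "collapse"),
    nodes = nodes), class = "interaction_network")
}

#' Build an interaction network from an explicit edge list
#'
#' @param edges Two-column matrix or data frame (source, target).
#' @param directed Logical.
#' @return An `interaction_network`.
#' @export
network_from_edges <- function(edges, directed = FALSE) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "character"
  edges <- unique(edges)
  nodes <- sort(unique(as.vector(edges)))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE), directed = directed,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  structure(list(
    graph = g,
    ugraph = igraph::as_undirected(igraph::simplify(g), mode = "collapse"),
    nodes = nodes), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Network topology summary
#'
#' Computed on the undirected simple view. Radius and diameter are taken
#' over the largest connected component; the average clustering coefficient
#' is the mean local clustering coefficient over all nodes, with nodes of
#' degree < 2 contributing 0. `avg_degree` is 2E/N; `avg_neighbors` is the
#' same quantity restricted to non-isolated nodes (the Cytoscape
#' "average number of neighbors" convention).
#'
#' @param network An `interaction_network`.
#' @return Named list: `n_nodes`, `n_edges`, `avg_degree`, `avg_neighbors`,
#'   `radius`, `diameter`, `avg_clustering`.
#' @export
topology_summary <- function(network) {
  u <- network$ugraph
  if (igraph::vcount(u) == 0) stop("empty network", call. = FALSE)
  comp <- igraph::components(u)
  giant <- igraph::induced_subgraph(
    u, which(comp$membership == which.max(comp$csize)))
  ecc <- igraph::eccentricity(giant)
  cc <- igraph::transitivity(u, type = "localundirected", isolates = "zero")
  cc[igraph::degree(u) < 2] <- 0
  deg <- igraph::degree(u)
  list(n_nodes = as.integer(igraph::vcount(u)),
       n_edges = as.integer(igraph::ecount(u)),
       avg_degree = 2 * igraph::ecount(u) / igraph::vcount(u),
       avg_neighbors = mean(deg[deg > 0]),
       radius = min(ecc),
       diameter = max(ecc),
       avg_clustering = mean(cc))
}

# ---- individual centrality implementations (undirected simple view) ----

# shortest-path dependencies: number of shortest s-t paths through v
# (sigma_st(v)) accumulated either raw (stress) or normalized
# (betweenness). Brandes' accumulation, BFS variant.
.path_counts <- function(u, normalized) {
  n <- igraph::vcount(u)
  score <- stats::setNames(numeric(n), igraph::V(u)$name)
  adj <- igraph::as_adj_list(u, mode = "all")
  adj <- lapply(adj, as.integer)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    order_seen <- integer(0)
    queue <- c(s)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_seen <- c(order_seen, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    delta <- numeric(n)
    for (v in rev(order_seen)) {
      for (w in adj[[v]]) {
        if (dist[w] == dist[v] + 1L) {
          contrib <- if (normalized) {
            sigma[v] / sigma[w] * (1 + delta[w])
          } else {
            sigma[v] * (1 + delta[w] / sigma[w])
          }
          delta[v] <- delta[v] + contrib
        }
      }
      if (v != s) score[v] <- score[v] + delta[v]
    }
  }
  score / 2  # each unordered pair visited from both endpoints
}

.centrality_degree <- function(u) igraph::degree(u)

# harmonic closeness: sum over reachable w of 1/d(v, w)
.centrality_closeness <- function(u) {
  igraph::harmonic_centrality(u, normalized = FALSE)
}

.centrality_betweenness <- function(u) .path_counts(u, normalized = TRUE)

.centrality_stress <- function(u) .path_counts(u, normalized = FALSE)

# 1/ecc(v) on the node's connected component
.centrality_eccentricity <- function(u) {
  ecc <- igraph::eccentricity(u, mode = "all")
  ifelse(ecc == 0, 1, 1 / ecc)
}

# radiality: sum_w (diam_comp + 1 - d(v,w)) / (n - 1), within components
.centrality_radiality <- function(u) {
  n <- igraph::vcount(u)
  out <- stats::setNames(numeric(n), igraph::V(u)$name)
  comp <- igraph::components(u)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) == 1) { out[idx] <- 0; next }
    sub <- igraph::induced_subgraph(u, idx)
    d <- igraph::distances(sub)
    diam <- max(d)
    out[idx] <- rowSums(diam + 1 - d) - (diam + 1)  # remove self term
    out[idx] <- out[idx] / (n - 1)
  }
  out
}

.centrality_clustering <- function(u) {
  cc <- igraph::transitivity(u, type = "localundirected", isolates = "zero")
  cc[igraph::degree(u) < 2] <- 0
  stats::setNames(cc, igraph::V(u)$name)
}

# size of the largest connected component of the open neighborhood
.centrality_mnc <- function(u) {
  vapply(seq_len(igraph::vcount(u)), function(v) {
    nb <- igraph::neighbors(u, v)
    if (length(nb) == 0) return(0)
    sub <- igraph::induced_subgraph(u, nb)
    max(igraph::components(sub)$csize)
  }, 0) |> stats::setNames(igraph::V(u)$name)
}

# DMNC: edges of the MNC subgraph divided by n_MNC^1.7
.centrality_dmnc <- function(u) {
  vapply(seq_len(igraph::vcount(u)), function(v) {
    nb <- igraph::neighbors(u, v)
    if (length(nb) == 0) return(0)
    sub <- igraph::induced_subgraph(u, nb)
    comp <- igraph::components(sub)
    big <- which.max(comp$csize)
    mncg <- igraph::induced_subgraph(sub, which(comp$membership == big))
    nm <- igraph::vcount(mncg)
    if (nm < 1) return(0)
    igraph::ecount(mncg) / nm^1.7
  }, 0) |> stats::setNames(igraph::V(u)$name)
}

# MCC: sum over maximal cliques C containing v of (|C|-1)!; when the only
# maximal cliques through v are single edges this reduces to deg(v)
.centrality_mcc <- function(u) {
  n <- igraph::vcount(u)
  out <- stats::setNames(numeric(n), igraph::V(u)$name)
  cliques <- igraph::max_cliques(u, min = 2)
  raw <- numeric(n)
  has_big <- logical(n)   # member of a maximal clique of size > 2
  for (cl in cliques) {
    sz <- length(cl)
    raw[as.integer(cl)] <- raw[as.integer(cl)] + factorial(sz - 1)
    if (sz > 2) has_big[as.integer(cl)] <- TRUE
  }
  deg <- igraph::degree(u)
  out[] <- ifelse(has_big, raw, deg)
  out
}

# bottleneck: for each root s, a node v owns the nodes whose shortest
# paths from s are all funneled through v (v dominates them in the
# shortest-path DAG, v itself included — the label-independent content of
# the "subtree of the shortest-path tree"); v scores +1 per root whose
# owned set exceeds a quarter of the component.
.centrality_bottleneck <- function(u) {
  n <- igraph::vcount(u)
  out <- stats::setNames(numeric(n), igraph::V(u)$name)
  adj <- lapply(igraph::as_adj_list(u, mode = "all"), as.integer)
  D <- matrix(Inf, n, n)
  Sg <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    queue <- c(s)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    D[s, ] <- dist
    Sg[s, ] <- sigma
  }
  comp <- igraph::components(u)
  for (s in seq_len(n)) {
    ncomp <- comp$csize[comp$membership[s]]
    for (v in seq_len(n)) {
      if (v == s || !is.finite(D[s, v])) next
      dominated <- is.finite(D[s, ]) &
        (D[s, v] + D[v, ] == D[s, ]) &
        (Sg[s, v] * Sg[v, ] == Sg[s, ])
      if (sum(dominated) > ncomp / 4) out[v] <- out[v] + 1
    }
  }
  out
}

# EPC: mean, over seeded random edge-retention realizations, of the size
# of the component containing v
.centrality_epc <- function(u, n_realizations = 1000,
                            keep_probability = 0.5, seed = NULL) {
  if (is.null(seed)) {
    stop("EPC requires an explicit seed for reproducibility", call. = FALSE)
  }
  n <- igraph::vcount(u)
  m <- igraph::ecount(u)
  acc <- stats::setNames(numeric(n), igraph::V(u)$name)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (i in seq_len(n_realizations)) {
    keep <- stats::runif(m) < keep_probability
    sub <- igraph::subgraph_from_edges(u, which(keep),
                                       delete.vertices = FALSE)
    comp <- igraph::components(sub)
    acc <- acc + comp$csize[comp$membership]
  }
  acc / n_realizations
}

#' Node centrality
#'
#' Computes one of the twelve CytoHubba-style centrality metrics on the
#' undirected simple view of the network: `degree`, `closeness` (harmonic,
#' robust to disconnection), `betweenness`, `bottleneck`,
#' `clustering_coefficient`, `mnc` (largest connected component of the
#' neighborhood), `dmnc` (edges of that component / size^1.7),
#' `eccentricity` (reciprocal of the longest shortest path from the node),
#' `epc` (edge-percolated component; requires a seed), `mcc` (maximal
#' clique centrality), `radiality`, and `stress` (raw shortest-path
#' counts).
#'
#' @param network An `interaction_network`.
#' @param metric One of [CENTRALITY_METRICS].
#' @param n_realizations,keep_probability,seed EPC parameters: number of
#'   random edge-retention realizations, per-edge retention probability,
#'   and the mandatory RNG seed.
#' @return Named numeric vector, one score per node.
#' @export
centrality <- function(network, metric, n_realizations = 1000,
                       keep_probability = 0.5, seed = NULL) {
  if (!metric %in% CENTRALITY_METRICS) {
    stop("unknown centrality metric: ", metric, call. = FALSE)
  }
  u <- network$ugraph
  switch(metric,
    degree = .centrality_degree(u),
    closeness = .centrality_closeness(u),
    betweenness = .centrality_betweenness(u),
    bottleneck = .centrality_bottleneck(u),
    clustering_coefficient = .centrality_clustering(u),
    mnc = .centrality_mnc(u),
    dmnc = .centrality_dmnc(u),
    eccentricity = .centrality_eccentricity(u),
    epc = .centrality_epc(u, n_realizations, keep_probability, seed),
    mcc = .centrality_mcc(u),
    radiality = .centrality_radiality(u),
    stress = .centrality_stress(u))
}

#' Full centrality table
#'
#' @param network An `interaction_network`.
#' @param epc_seed Seed forwarded to the EPC metric.
#' @param epc_realizations Number of EPC realizations.
#' @return Data frame, one row per node, one column per metric.
#' @export
centrality_table <- function(network, epc_seed = 1,
                             epc_realizations = 1000) {
  cols <- lapply(CENTRALITY_METRICS, function(m) {
    if (m == "epc") {
      centrality(network, m, n_realizations = epc_realizations,
                 seed = epc_seed)
    } else {
      centrality(network, m)
    }
  })
  names(cols) <- CENTRALITY_METRICS
  out <- data.frame(node = network$nodes, stringsAsFactors = FALSE)
  for (m in CENTRALITY_METRICS) out[[m]] <- unname(cols[[m]][network$nodes])
  out
}

#' Hub frequency of occurrence
#'
#' For each centrality metric, the top `k` nodes are taken (ties broken by
#' node id); a node's frequency is the number of metrics in whose top-k
#' list it appears, between 0 and 12. The report is ranked by descending
#' frequency, then id.
#'
#' @param centrality_table Data frame from [centrality_table()].
#' @param k Top-list size per metric (default 20).
#' @return Data frame (node, frequency), ranked.
#' @export
hub_frequency <- function(centrality_table, k = 20) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  metrics <- setdiff(names(centrality_table), "node")
  nodes <- centrality_table$node
  freq <- stats::setNames(integer(length(nodes)), nodes)
  for (m in metrics) {
    ord <- order(-centrality_table[[m]], nodes)
    top <- nodes[ord][seq_len(min(k, length(nodes)))]
    freq[top] <- freq[top] + 1L
  }
  out <- data.frame(node = nodes, frequency = unname(freq),
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$node), , drop = FALSE]
}

#' Export a network as an edge-list data frame
#'
#' @param network An `interaction_network`.
#' @return Data frame (source, target) of the directed deduplicated graph.
#' @export
network_edges <- function(network) {
  e <- igraph::as_edgelist(network$graph)
  data.frame(source = e[, 1], target = e[, 2], stringsAsFactors = FALSE)
}

#' Write a network to disk
#'
#' @param network An `interaction_network`.
#' @param path Output file.
#' @param format `"csv"` (two-column edge list) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(network_edges(network), path, row.names = FALSE)
  } else {
    igraph::write_graph(network$graph, path, format = "graphml")
  }
  invisible(path)
}
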