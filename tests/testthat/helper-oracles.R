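# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph where the metric itself is under test):
# distances and path counts come from breadth-first enumeration over an
# adjacency matrix, cliques from exhaustive subset enumeration, components
# from a hand-rolled flood fill.

oracle_adjacency <- function(network) {
  g <- network$ugraph
  am <- matrix(0L, igraph::vcount(g), igraph::vcount(g),
               dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) {
    am[el[i, 1], el[i, 2]] <- 1L
    am[el[i, 2], el[i, 1]] <- 1L
  }
  am
}

# all shortest paths between two nodes by recursive backtracking over BFS
# distance layers
oracle_all_shortest_paths <- function(am, s, t) {
  n <- nrow(am)
  dist <- rep(Inf, n); dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in which(am[v, ] == 1L)) {
        if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      }
    }
    frontier <- unique(nxt)
  }
  if (!is.finite(dist[t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == s) { paths[[length(paths) + 1]] <<- rev(acc); return() }
    for (w in which(am[v, ] == 1L)) {
      if (dist[w] == dist[v] - 1) walk(w, c(acc, w))
    }
  }
  walk(t, c(t))
  paths
}

# betweenness and stress by full path enumeration
oracle_betweenness_stress <- function(network) {
  am <- oracle_adjacency(network)
  n <- nrow(am)
  bet <- stats::setNames(numeric(n), rownames(am))
  str <- stats::setNames(numeric(n), rownames(am))
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_all_shortest_paths(am, s, t)
    if (length(paths) == 0) next
    thru <- table(unlist(lapply(paths, function(p) setdiff(p, c(s, t)))))
    if (length(thru)) {
      idx <- as.integer(names(thru))
      bet[idx] <- bet[idx] + as.numeric(thru) / length(paths)
      str[idx] <- str[idx] + as.numeric(thru)
    }
  }
  list(betweenness = bet, stress = str)
}

# maximal cliques by subset enumeration (n <= ~15)
oracle_max_cliques <- function(am) {
  n <- nrow(am)
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    nodes <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(nodes) < 2) next
    pairs <- utils::combn(nodes, 2)
    is_clique <- all(am[t(pairs)] == 1L)
    if (!is_clique) next
    # maximal: no outside vertex adjacent to all members
    extendable <- any(vapply(setdiff(seq_len(n), nodes), function(v) {
      all(am[v, nodes] == 1L)
    }, TRUE))
    if (!extendable) cliques[[length(cliques) + 1]] <- nodes
  }
  cliques
}

oracle_mcc <- function(network) {
  am <- oracle_adjacency(network)
  n <- nrow(am)
  out <- stats::setNames(numeric(n), rownames(am))
  cliques <- oracle_max_cliques(am)
  in_big <- rep(FALSE, n)
  raw <- numeric(n)
  for (cl in cliques) {
    raw[cl] <- raw[cl] + factorial(length(cl) - 1)
    if (length(cl) > 2) in_big[cl] <- TRUE
  }
  deg <- rowSums(am)
  out[] <- ifelse(in_big, raw, deg)
  out
}

oracle_components <- function(am, nodes = seq_len(nrow(am))) {
  comp <- rep(0L, nrow(am))
  cur <- 0L
  for (s in nodes) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, intersect(which(am[v, ] == 1L), nodes))
    }
  }
  comp[nodes]
}

oracle_mnc_dmnc <- function(network) {
  am <- oracle_adjacency(network)
  n <- nrow(am)
  mnc <- stats::setNames(numeric(n), rownames(am))
  dmnc <- stats::setNames(numeric(n), rownames(am))
  for (v in seq_len(n)) {
    nb <- which(am[v, ] == 1L)
    if (length(nb) == 0) next
    comp <- oracle_components(am, nb)
    sizes <- tabulate(comp)
    big <- which.max(sizes)
    members <- nb[comp == big]
    mnc[v] <- length(members)
    if (length(members) >= 1) {
      sub <- am[members, members, drop = FALSE]
      dmnc[v] <- (sum(sub) / 2) / length(members)^1.7
    }
  }
  list(mnc = mnc, dmnc = dmnc)
}

# Relative errors of forward sensitivities against the central
# finite-difference oracle, restricted to significant entries: with
# molecule-count states the FD quotient has a noise floor of roughly
# solver_error / (2 * 1e-6 * p), so entries whose dedimensionalized
# magnitude |S| * p / max|x| falls below 1e-4 are indistinguishable from
# that noise and are excluded from the comparison.
fd_relative_errors <- function(model, input, tensor, t_end) {
  fd <- oracle_fd_sensitivity(model, input, t_end,
                              n_out = length(tensor$time))
  got <- tensor$values[, , which(tensor$inputs == input)]
  p0 <- if (grepl("^x0\\.", input)) {
    sp <- sub("^x0\\.", "", input)
    Filter(function(s) s$id == sp, model$species)[[1]]$initial_amount
  } else {
    parts <- strsplit(input, ".", fixed = TRUE)[[1]]
    Filter(function(r) r$id == parts[1],
           model$reactions)[[1]]$rate$parameters[[parts[2]]]
  }
  xscale <- pmax(apply(simulate_model(model, t_end = t_end,
                                      n_out = 3)$states, 2, max), 1)
  scale <- matrix(xscale, nrow(fd), ncol(fd), byrow = TRUE)
  sig <- abs(fd) * p0 / scale > 1e-4
  if (!any(sig)) return(numeric(0))
  abs(got - fd)[sig] / abs(fd)[sig]
}

# Central finite differences of final states w.r.t. one input, using
# tight-tolerance integrations (the oracle for forward sensitivities).
# The relative step 1e-3 balances truncation error (~step^2) against the
# solver-noise amplification (~rel_tol/step): rate constants span many
# decades here, and a much smaller step drowns small-parameter columns
# in integration noise.
oracle_fd_sensitivity <- function(model, input, t_end, n_out = 3,
                                  rel_step = 1e-3) {
  run <- function(mod) {
    simulate_model(mod, t_end = t_end, rel_tol = 1e-11, abs_tol = 1e-12,
                   n_out = n_out)$states
  }
  if (grepl("^x0\\.", input)) {
    sp <- sub("^x0\\.", "", input)
    p0 <- NULL
    for (s in model$species) if (s$id == sp) p0 <- s$initial_amount
    dp <- max(rel_step * p0, 1e-6)
    bump <- function(d) {
      for (i in seq_along(model$species)) {
        if (model$species[[i]]$id == sp) {
          model$species[[i]]$initial_amount <- p0 + d
        }
      }
      model
    }
  } else {
    parts <- strsplit(input, ".", fixed = TRUE)[[1]]
    p0 <- NULL
    for (rx in model$reactions) {
      if (rx$id == parts[1]) p0 <- rx$rate$parameters[[parts[2]]]
    }
    dp <- rel_step * p0
    bump <- function(d) {
      for (i in seq_along(model$reactions)) {
        if (model$reactions[[i]]$id == parts[1]) {
          model$reactions[[i]]$rate$parameters[[parts[2]]] <- p0 + d
        }
      }
      model
    }
  }
  (run(bump(dp)) - run(bump(-dp))) / (2 * dp)
}
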