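# Seeded generators of random kinetic models and random graphs with the
# structural statistics the analyses assume: multiple compartments, the
# three rate-law families, initial abundances in the 10^3-10^6 molecule
# band, and connected reaction graphs. Determinism under seed is the
# master invariant.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Specification for the random-model generator
#'
#' @param n_compartments,n_species,n_reactions Model size.
#' @param rate_law_mix Proportions over (mass_action, michaelis_menten,
#'   hill); must sum to 1.
#' @param initial_amount_range Range the initial molecule counts are
#'   drawn from, log-uniformly (default 10^3-10^6, the band signaling
#'   species occupy).
#' @param balanced If `TRUE`, every mass-action reaction carries equal
#'   total stoichiometry on both sides, so closed mass-action models
#'   conserve total mass.
#' @param seed Integer seed; the same spec and seed reproduce the model
#'   exactly.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_compartments = 2, n_species = 8,
                           n_reactions = 10,
                           rate_law_mix = c(mass_action = 0.7,
                                            michaelis_menten = 0.15,
                                            hill = 0.15),
                           initial_amount_range = c(1e3, 1e6),
                           balanced = FALSE, seed = 1) {
  if (abs(sum(rate_law_mix) - 1) > 1e-9) {
    stop("rate_law_mix must sum to 1", call. = FALSE)
  }
  if (n_reactions < 1 || n_species < 2) {
    stop("need at least 2 species and 1 reaction", call. = FALSE)
  }
  structure(list(n_compartments = n_compartments, n_species = n_species,
                 n_reactions = n_reactions,
                 rate_law_mix = rate_law_mix,
                 initial_amount_range = initial_amount_range,
                 balanced = isTRUE(balanced), seed = seed),
            class = "generator_spec")
}

#' Generate a random kinetic model
#'
#' Species are distributed over the compartments and connected by a
#' spanning construction: each of the first reactions links a not yet
#' used species to the already connected core, which guarantees a
#' connected reaction graph and that every species takes part in some
#' reaction. Stoichiometries are limited to 1 and 2 reactants/products.
#' Hill reactions follow the gene-template convention (a conserved
#' template species plus a modifier driving expression), so generated
#' models stay non-negative under integration.
#'
#' @param spec A [generator_spec()].
#' @return A validated `reaction_model`.
#' @export
random_model <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    nc <- spec$n_compartments
    ns <- spec$n_species
    comps <- lapply(seq_len(nc), function(i) {
      compartment(sprintf("c%02d", i), sprintf("compartment %d", i),
                  COMPARTMENT_KINDS[(i - 1) %% 6 + 1])
    })
    x0 <- runif_log(ns, spec$initial_amount_range[1],
                    spec$initial_amount_range[2])
    species <- lapply(seq_len(ns), function(i) {
      species_state(sprintf("s%02d", i), sprintf("species %d", i),
                    sprintf("c%02d", (i - 1) %% nc + 1), x0[i])
    })
    sp_ids <- vapply(species, `[[`, "", "id")

    kinds <- sample(names(spec$rate_law_mix), spec$n_reactions,
                    replace = TRUE, prob = spec$rate_law_mix)
    connected <- sp_ids[1]
    pending <- sp_ids[-1]
    reactions <- vector("list", spec$n_reactions)
    pick <- function(pool, n) pool[sample.int(length(pool), n)]
    # pending species are scheduled over the remaining reactions so the
    # spanning construction is guaranteed to absorb them all; fresh
    # species always enter on the product side, keeping every species
    # reachable from the connected core
    for (j in seq_len(spec$n_reactions)) {
      left <- spec$n_reactions - j + 1L
      must_take <- max(0L, length(pending) - 2L * (left - 1L))
      take <- min(length(pending),
                  max(must_take, sample(0:2, 1,
                                        prob = c(0.3, 0.5, 0.2))))
      fresh <- if (take > 0) pick(pending, take) else character()
      pending <- setdiff(pending, fresh)
      kind <- kinds[j]
      if (kind == "mass_action") {
        n_re <- sample(1:2, 1)
        n_pr <- max(length(fresh), sample(1:2, 1))
        re_pool <- pick(connected, min(n_re, length(connected)))
        prods <- unique(c(fresh, pick(setdiff(sp_ids, re_pool),
                                      n_pr)))[seq_len(n_pr)]
        prods <- prods[!is.na(prods)]
        re_st <- rep(1L, length(re_pool))
        pr_st <- rep(1L, length(prods))
        if (spec$balanced) {
          # equalize total stoichiometry so molecule count is conserved
          if (sum(re_st) < sum(pr_st)) re_st[1] <- re_st[1] +
              sum(pr_st) - sum(re_st)
          if (sum(pr_st) < sum(re_st)) pr_st[1] <- pr_st[1] +
              sum(re_st) - sum(pr_st)
        }
        rx <- reaction(sprintf("r%02d", j),
                       sprintf("r%02d: %s -> %s", j,
                               paste(re_pool, collapse = "+"),
                               paste(prods, collapse = "+")),
                       reactants = stats::setNames(re_st, re_pool),
                       products = stats::setNames(pr_st, prods),
                       rate = rate_law("mass_action",
                                       k = if (sum(re_st) == 1) {
                                         runif_log(1, 1e-3, 1e-1)
                                       } else runif_log(1, 1e-9, 1e-6)))
      } else if (kind == "michaelis_menten") {
        sub <- pick(connected, 1)
        prods <- if (length(fresh)) fresh else
          pick(setdiff(sp_ids, sub), 1)
        rx <- reaction(sprintf("r%02d", j),
                       sprintf("r%02d: %s -> %s (MM)", j, sub,
                               paste(prods, collapse = "+")),
                       reactants = stats::setNames(1L, sub),
                       products = stats::setNames(rep(1L, length(prods)),
                                                  prods),
                       rate = rate_law("michaelis_menten",
                                       Vmax = runif_log(1, 1e2, 1e4),
                                       Km = runif_log(1, 1e3, 1e6)))
      } else {
        tmpl <- pick(connected, 1)
        driver <- if (length(connected) > 1) {
          pick(setdiff(connected, tmpl), 1)
        } else tmpl
        prods <- if (length(fresh)) fresh else
          pick(setdiff(sp_ids, c(tmpl, driver)), 1)
        rx <- reaction(sprintf("r%02d", j),
                       sprintf("r%02d: %s + %s -> %s + %s (hill)", j,
                               driver, tmpl, tmpl,
                               paste(prods, collapse = "+")),
                       reactants = stats::setNames(1L, tmpl),
                       products = stats::setNames(rep(1L,
                                                      length(prods) + 1L),
                                                  c(tmpl, prods)),
                       modifiers = driver,
                       rate = rate_law("hill",
                                       Vmax = runif_log(1, 1e2, 1e4),
                                       K = runif_log(1, 1e3, 1e6),
                                       n = sample(1:2, 1)))
      }
      reactions[[j]] <- rx
      connected <- unique(c(connected, names(rx$reactants),
                            names(rx$products), rx$modifiers))
    }
    m <- reaction_model(comps, species, reactions,
                        name = sprintf("synthetic model (seed %d)",
                                       spec$seed))
    assert_valid(m)
    m
  })
}

#' Perturb a model's rate parameters
#'
#' Each parameter is multiplied by `exp(u)` with
#' `u ~ uniform(-relative_scale, relative_scale)`; the structure is
#' unchanged. Same seed, same perturbation.
#'
#' @param model A `reaction_model`.
#' @param relative_scale Scale in (0, 1).
#' @param seed Integer seed.
#' @return The perturbed `reaction_model`.
#' @export
perturb_model <- function(model, relative_scale, seed) {
  stopifnot(relative_scale > 0, relative_scale < 1)
  with_seed(seed, {
    for (j in seq_along(model$reactions)) {
      p <- model$reactions[[j]]$rate$parameters
      model$reactions[[j]]$rate$parameters <-
        p * exp(stats::runif(length(p), -relative_scale, relative_scale))
    }
    model
  })
}

#' Seeded Erdős–Rényi random graph
#'
#' @param n Number of nodes (labelled `n01`, `n02`, ...).
#' @param p Edge probability.
#' @param seed Integer seed.
#' @return An `interaction_network` (undirected simple graph).
#' @export
random_graph <- function(n, p, seed) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  with_seed(seed, {
    g <- igraph::sample_gnp(n, p, directed = FALSE)
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    structure(list(graph = g, ugraph = g,
                   nodes = igraph::V(g)$name),
              class = "interaction_network")
  })
}
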