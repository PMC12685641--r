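# Core data structures for compartmental kinetic models: compartments,
# species, typed rate laws, reactions, and whole-model validation.

COMPARTMENT_KINDS <- c("cytoplasm", "plasma_membrane", "nucleus",
                       "endoplasmic_reticulum", "golgi", "ergic", "other")
RATE_LAW_KINDS <- c("mass_action", "michaelis_menten", "hill")

#' Create a compartment
#'
#' @param id Short unique identifier.
#' @param name Display name.
#' @param kind One of `"cytoplasm"`, `"plasma_membrane"`, `"nucleus"`,
#'   `"endoplasmic_reticulum"`, `"golgi"`, `"ergic"`, `"other"`.
#' @return A `compartment` object.
#' @export
compartment <- function(id, name = id, kind = "other") {
  kind <- match.arg(kind, COMPARTMENT_KINDS)
  structure(list(id = id, name = name, kind = kind), class = "compartment")
}

#' Create a species state
#'
#' Amounts are dimensionless molecule counts; compartment volumes are fixed
#' at 1 so amount and concentration coincide. Boundary species (gene loci,
#' constant external pools) are held fixed during simulation.
#'
#' @param id Short unique identifier.
#' @param name Display name.
#' @param compartment Compartment id the species lives in.
#' @param initial_amount Non-negative initial molecule count.
#' @param boundary Logical; `TRUE` for species held constant.
#' @return A `species_state` object.
#' @export
species_state <- function(id, name = id, compartment, initial_amount,
                          boundary = FALSE) {
  if (!is.numeric(initial_amount) || length(initial_amount) != 1 ||
      is.na(initial_amount) || initial_amount < 0) {
    stop("initial_amount must be a single non-negative number", call. = FALSE)
  }
  structure(list(id = id, name = name, compartment = compartment,
                 initial_amount = as.numeric(initial_amount),
                 boundary = isTRUE(boundary)),
            class = "species_state")
}

#' Create a rate law
#'
#' Three families are supported, following the usual assignment conventions
#' for signaling models: mass action for association, dissociation and
#' translocation; Michaelis-Menten for enzymatic conversion; Hill kinetics
#' for gene-expression reactions driven by a transcription factor.
#'
#' @param kind One of `"mass_action"` (parameter `k`),
#'   `"michaelis_menten"` (`Vmax`, `Km`) or `"hill"` (`Vmax`, `K`, `n`).
#' @param k,Vmax,Km,K,n Numeric parameters for the chosen family.
#' @return A `rate_law` object.
#' @examples
#' rate_law("mass_action", k = 0.5)
#' rate_law("hill", Vmax = 10, K = 1e4, n = 2)
#' @export
rate_law <- function(kind, k = NULL, Vmax = NULL, Km = NULL, K = NULL,
                     n = NULL) {
  if (!is.character(kind) || !kind %in% RATE_LAW_KINDS) {
    stop("unknown rate-law kind: ", kind, call. = FALSE)
  }
  pars <- unlist(Filter(Negate(is.null),
                        list(k = k, Vmax = Vmax, Km = Km, K = K, n = n)))
  required <- switch(kind,
    mass_action = "k",
    michaelis_menten = c("Vmax", "Km"),
    hill = c("Vmax", "K", "n"))
  missing <- setdiff(required, names(pars))
  if (length(missing)) {
    stop(kind, " rate law needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pars <- pars[required]
  if (any(!is.finite(pars)) || any(pars <= 0)) {
    stop("rate-law parameters must be positive and finite", call. = FALSE)
  }
  structure(list(kind = kind, parameters = pars), class = "rate_law")
}

#' Create a reaction
#'
#' Reactants and products are given as named integer vectors of
#' stoichiometries (`c(A = 1, B = 2)`). Modifiers are catalyst species that
#' appear unchanged — transcription factors for Hill reactions, enzymes
#' annotated on Michaelis-Menten or mass-action steps. A species listed on
#' both reactant and product side acts as a conserved template (gene loci,
#' catalytic complexes).
#'
#' @param id Short unique identifier.
#' @param name Human-readable equation string, e.g.
#'   `"LC3/ATG12/5/16L -> Autophagosome"`.
#' @param reactants,products Named integer vectors (species id ->
#'   stoichiometry). At least one product is required.
#' @param modifiers Character vector of catalyst species ids.
#' @param rate Object created by [rate_law()].
#' @param reversible Logical; the curated model uses irreversible steps only.
#' @return A `reaction` object.
#' @export
reaction <- function(id, name = id, reactants = integer(), products,
                     modifiers = character(), rate, reversible = FALSE) {
  stopifnot(inherits(rate, "rate_law"))
  norm <- function(x) {
    if (length(x) == 0) return(stats::setNames(integer(), character()))
    if (is.null(names(x)) || any(names(x) == "")) {
      stop("reactants/products must be named (species id -> stoichiometry)",
           call. = FALSE)
    }
    if (any(x < 1) || any(x != round(x))) {
      stop("stoichiometries must be positive integers", call. = FALSE)
    }
    stats::setNames(as.integer(x), names(x))
  }
  products <- norm(products)
  if (length(products) == 0) {
    stop("a reaction needs at least one product", call. = FALSE)
  }
  structure(list(id = id, name = name, reactants = norm(reactants),
                 products = products, modifiers = as.character(modifiers),
                 rate = rate, reversible = isTRUE(reversible)),
            class = "reaction")
}

#' Assemble a reaction model
#'
#' @param compartments List of [compartment()] objects.
#' @param species List of [species_state()] objects.
#' @param reactions List of [reaction()] objects.
#' @param pathway_tags Named list mapping species id to a character vector of
#'   pathway names (used by crosstalk scoring).
#' @param name Model display name.
#' @param t_end Default simulation horizon in seconds.
#' @param notes Free-text provenance notes.
#' @return A `reaction_model` object.
#' @export
reaction_model <- function(compartments, species, reactions,
                           pathway_tags = list(), name = "model",
                           t_end = 100, notes = character()) {
  m <- structure(
    list(compartments = compartments, species = species,
         reactions = reactions, pathway_tags = pathway_tags,
         metadata = list(name = name, t_end = t_end, notes = notes)),
    class = "reaction_model")
  ids <- species_ids(m)
  if (anyDuplicated(ids)) {
    stop("duplicate species ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cids <- vapply(compartments, `[[`, "", "id")
  if (anyDuplicated(cids)) stop("duplicate compartment ids", call. = FALSE)
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids", call. = FALSE)
  m
}

#' @export
print.reaction_model <- function(x, ...) {
  cat(sprintf("<reaction_model> %s\n", x$metadata$name))
  cat(sprintf("  compartments: %d\n", length(x$compartments)))
  cat(sprintf("  species: %d dynamic + %d boundary\n",
              n_species(x), sum(vapply(x$species, `[[`, TRUE, "boundary"))))
  cat(sprintf("  reactions: %d\n", length(x$reactions)))
  invisible(x)
}

#' Species / reaction accessors
#'
#' `species_ids()` returns ids of all species states (dynamic and boundary);
#' `n_species()` counts the dynamic signaling species only — boundary gene
#' loci and constant external pools are templates, not state variables — so
#' the census of the curated model reads (6 compartments, 72 species, 83
#' reactions). `reaction_ids()` and `reaction_names()` enumerate reactions.
#'
#' @param model A `reaction_model`.
#' @return Character vector (ids/names) or integer count.
#' @export
species_ids <- function(model) vapply(model$species, `[[`, "", "id")

#' @rdname species_ids
#' @export
n_species <- function(model) {
  sum(!vapply(model$species, `[[`, TRUE, "boundary"))
}

#' @rdname species_ids
#' @export
reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

#' @rdname species_ids
#' @export
reaction_names <- function(model) vapply(model$reactions, `[[`, "", "name")

boundary_ids <- function(model) {
  species_ids(model)[vapply(model$species, `[[`, TRUE, "boundary")]
}

initial_state <- function(model) {
  stats::setNames(vapply(model$species, `[[`, 0, "initial_amount"),
                  species_ids(model))
}

#' Evaluate the instantaneous rate of a reaction
#'
#' Mass action: `k * prod(reactant^stoich)`. Michaelis-Menten:
#' `Vmax * S / (Km + S)` with `S` the single substrate. Hill:
#' `Vmax * S^n / (K^n + S^n)` with `S` the driving species — the single
#' modifier if one is declared (transcription-factor convention), otherwise
#' the single substrate. Hill with `n = 1` reduces exactly to
#' Michaelis-Menten with `Km = K`.
#'
#' @param reaction A `reaction` object.
#' @param state Named numeric vector of species amounts; must cover every
#'   species the rate references.
#' @return Non-negative finite rate in mol/s.
#' @export
evaluate_rate <- function(reaction, state) {
  law <- reaction$rate
  p <- law$parameters
  need <- union(names(reaction$reactants), reaction$modifiers)
  miss <- setdiff(need, names(state))
  if (length(miss)) {
    stop("state is missing species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v <- switch(law$kind,
    mass_action = {
      x <- state[names(reaction$reactants)]
      p[["k"]] * prod(x ^ reaction$reactants)
    },
    michaelis_menten = {
      S <- state[[driving_species(reaction)]]
      p[["Vmax"]] * S / (p[["Km"]] + S)
    },
    hill = {
      S <- state[[driving_species(reaction)]]
      Sn <- S ^ p[["n"]]
      p[["Vmax"]] * Sn / (p[["K"]] ^ p[["n"]] + Sn)
    },
    stop("unknown rate-law kind: ", law$kind, call. = FALSE))
  v <- unname(v)
  if (!is.finite(v)) {
    stop(sprintf("reaction '%s': non-finite rate", reaction$id),
         call. = FALSE)
  }
  v
}

# The species whose amount enters a saturating rate law. Michaelis-Menten
# reads its single substrate (non-template reactant); Hill reads the single
# modifier when one is declared (transcription-factor convention), falling
# back to the substrate. Template species appearing on both sides (gene
# loci, catalytic complexes) never drive a saturating law.
driving_species <- function(reaction) {
  subs <- setdiff(names(reaction$reactants), names(reaction$products))
  s <- if (reaction$rate$kind == "hill" && length(reaction$modifiers) == 1) {
    reaction$modifiers
  } else {
    subs
  }
  if (length(s) != 1) {
    stop(sprintf("reaction '%s': %s kinetics need exactly one driving species",
                 reaction$id, reaction$rate$kind), call. = FALSE)
  }
  s
}

#' Validate a reaction model
#'
#' Returns findings rather than raising: errors for unresolved species ids,
#' non-positive rate parameters, malformed Michaelis-Menten/Hill driver
#' declarations; warnings for dynamic species whose initial amount lies
#' outside the 10^3-10^6 molecule band that signaling species are expected
#' to occupy.
#'
#' @param model A `reaction_model`.
#' @return Data frame with columns `level` ("error"/"warning"), `where`,
#'   `message`. Zero rows means a clean model.
#' @export
validate_model <- function(model) {
  findings <- list()
  add <- function(level, where, msg) {
    findings[[length(findings) + 1]] <<- data.frame(
      level = level, where = where, message = msg,
      stringsAsFactors = FALSE)
  }
  ids <- species_ids(model)
  cids <- vapply(model$compartments, `[[`, "", "id")
  for (sp in model$species) {
    if (!sp$compartment %in% cids) {
      add("error", sp$id, sprintf("unknown compartment '%s'", sp$compartment))
    }
    if (sp$initial_amount < 0) {
      add("error", sp$id, "negative initial amount")
    } else if (!sp$boundary &&
               (sp$initial_amount < 1e3 || sp$initial_amount > 1e6)) {
      add("warning", sp$id,
          sprintf("initial amount %.3g outside 10^3-10^6 band",
                  sp$initial_amount))
    }
  }
  for (rx in model$reactions) {
    refs <- unique(c(names(rx$reactants), names(rx$products), rx$modifiers))
    miss <- setdiff(refs, ids)
    for (mm in miss) add("error", rx$id, sprintf("unresolved species '%s'", mm))
    if (any(rx$rate$parameters <= 0) || any(!is.finite(rx$rate$parameters))) {
      add("error", rx$id, "non-positive rate parameter")
    }
    if (rx$rate$kind %in% c("michaelis_menten", "hill") &&
        length(miss) == 0) {
      ok <- tryCatch({ driving_species(rx); TRUE }, error = function(e) FALSE)
      if (!ok) {
        add("error", rx$id,
            sprintf("%s kinetics need exactly one driving species",
                    rx$rate$kind))
      }
    }
    if (length(rx$products) == 0) add("error", rx$id, "no product")
  }
  if (length(findings) == 0) {
    return(data.frame(level = character(), where = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

assert_valid <- function(model) {
  f <- validate_model(model)
  errs <- f[f$level == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("model has validation errors:\n",
         paste(sprintf("  [%s] %s", errs$where, errs$message),
               collapse = "\n"), call. = FALSE)
  }
  invisible(model)
}

#' Stoichiometric matrix
#'
#' Net stoichiometry (products minus reactants) with one row per species and
#' one column per reaction. Boundary species rows are zeroed: their amounts
#' are clamped.
#'
#' @param model A `reaction_model`.
#' @return Numeric matrix, species x reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  ids <- species_ids(model)
  N <- matrix(0, length(ids), length(model$reactions),
              dimnames = list(ids, reaction_ids(model)))
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    for (s in names(rx$reactants)) {
      N[s, j] <- N[s, j] - rx$reactants[[s]]
    }
    for (s in names(rx$products)) {
      N[s, j] <- N[s, j] + rx$products[[s]]
    }
  }
  N[boundary_ids(model), ] <- 0
  N
}

#' Export species and reaction tables
#'
#' @param model A `reaction_model`.
#' @return `species_table()`: data frame (id, name, compartment,
#'   initial_amount, boundary). `reaction_table()`: data frame (id, name,
#'   rate_kind, parameters as "k=0.1"-style strings).
#' @export
species_table <- function(model) {
  data.frame(
    id = species_ids(model),
    name = vapply(model$species, `[[`, "", "name"),
    compartment = vapply(model$species, `[[`, "", "compartment"),
    initial_amount = vapply(model$species, `[[`, 0, "initial_amount"),
    boundary = vapply(model$species, `[[`, TRUE, "boundary"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname species_table
#' @export
reaction_table <- function(model) {
  data.frame(
    id = reaction_ids(model),
    name = reaction_names(model),
    rate_kind = vapply(model$reactions, function(r) r$rate$kind, ""),
    parameters = vapply(model$reactions, function(r) {
      paste(sprintf("%s=%.15g", names(r$rate$parameters),
                    r$rate$parameters), collapse = ";")
    }, ""),
    row.names = NULL, stringsAsFactors = FALSE)
}
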