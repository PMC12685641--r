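# SBML Level 3 Version 2 exchange for reaction models. The writer emits
# the three kinetic-law families as canonical MathML with local
# parameters; the reader accepts exactly this subset and reports an
# unsupported-construct error (naming the reaction) for anything else.
# Pathway tags and the time horizon travel in a package annotation
# namespace.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
.ANN_NS <- "https://r-pkg.invalid/stingfoxo/annotation"

num_attr <- function(x) sprintf("%.17g", x)

#' Write a model as SBML Level 3 Version 2
#'
#' @param model A validated `reaction_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  assert_valid(model)
  doc <- xml2::xml_new_root("sbml", xmlns = .SBML_NS,
                            "xmlns:sf" = .ANN_NS,
                            level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             name = model$metadata$name)
  ann <- xml2::xml_add_child(mdl, "annotation")
  meta <- xml2::xml_add_child(ann, "sf:meta",
                              t_end = num_attr(model$metadata$t_end))
  if (length(model$metadata$notes)) {
    xml2::xml_set_attr(meta, "notes",
                       paste(model$metadata$notes, collapse = " "))
  }
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in model$compartments) {
    xml2::xml_add_child(lc, "compartment", id = cp$id, name = cp$name,
                        spatialDimensions = "3", size = "1",
                        constant = "true", "sf:kind" = cp$kind)
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (sp in model$species) {
    node <- xml2::xml_add_child(
      ls, "species", id = sp$id, name = sp$name,
      compartment = sp$compartment,
      initialAmount = num_attr(sp$initial_amount),
      hasOnlySubstanceUnits = "true",
      boundaryCondition = if (sp$boundary) "true" else "false",
      constant = "false")
    tags <- model$pathway_tags[[sp$id]]
    if (length(tags)) {
      a <- xml2::xml_add_child(node, "annotation")
      pw <- xml2::xml_add_child(a, "sf:pathways")
      for (tg in tags) xml2::xml_add_child(pw, "sf:pathway", tg)
    }
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (rx in model$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction", id = rx$id, name = rx$name,
                              reversible = if (rx$reversible) "true" else
                                "false")
    if (length(rx$reactants)) {
      l <- xml2::xml_add_child(rn, "listOfReactants")
      for (s in names(rx$reactants)) {
        xml2::xml_add_child(l, "speciesReference", species = s,
                            stoichiometry = num_attr(rx$reactants[[s]]),
                            constant = "true")
      }
    }
    l <- xml2::xml_add_child(rn, "listOfProducts")
    for (s in names(rx$products)) {
      xml2::xml_add_child(l, "speciesReference", species = s,
                          stoichiometry = num_attr(rx$products[[s]]),
                          constant = "true")
    }
    if (length(rx$modifiers)) {
      l <- xml2::xml_add_child(rn, "listOfModifiers")
      for (s in rx$modifiers) {
        xml2::xml_add_child(l, "modifierSpeciesReference", species = s)
      }
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = .MATHML_NS)
    .add_rate_math(math, rx)
    lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
    for (pn in names(rx$rate$parameters)) {
      xml2::xml_add_child(lp, "localParameter", id = pn,
                          value = num_attr(rx$rate$parameters[[pn]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# canonical MathML for the three families
.add_rate_math <- function(math, rx) {
  ci <- function(parent, x) {
    xml2::xml_set_text(xml2::xml_add_child(parent, "ci"), x)
  }
  pow <- function(parent, base, expo) {
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, "power")
    ci(ap, base); ci(ap, expo)
  }
  kind <- rx$rate$kind
  if (kind == "mass_action") {
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    ci(ap, "k")
    for (s in names(rx$reactants)) {
      st <- rx$reactants[[s]]
      if (st == 1) ci(ap, s) else {
        p <- xml2::xml_add_child(ap, "apply")
        xml2::xml_add_child(p, "power")
        ci(p, s)
        xml2::xml_set_text(xml2::xml_add_child(p, "cn",
                                               type = "integer"),
                           as.character(st))
      }
    }
  } else {
    drv <- driving_species(rx)
    div <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(div, "divide")
    num <- xml2::xml_add_child(div, "apply")
    xml2::xml_add_child(num, "times")
    ci(num, "Vmax")
    den <- xml2::xml_add_child(div, "apply")
    xml2::xml_add_child(den, "plus")
    if (kind == "michaelis_menten") {
      ci(num, drv)
      ci(den, "Km"); ci(den, drv)
    } else {
      pow(num, drv, "n")
      pow(den, "K", "n"); pow(den, drv, "n")
    }
  }
}

#' Read a model from SBML
#'
#' Accepts the SBML Level 3 subset produced by [write_model()]: the three
#' kinetic-law families with local parameters. A malformed file raises a
#' parse error with line context; a kinetic law outside the supported
#' families raises an unsupported-construct error naming the reaction.
#'
#' @param path SBML file path.
#' @return A `reaction_model`.
#' @export
read_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop(sprintf("SBML parse error in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  ns <- c(s = .SBML_NS, sf = .ANN_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(mdl, ns))) {
    stop(sprintf("SBML parse error in '%s': no <model> element", path),
         call. = FALSE)
  }
  meta <- xml2::xml_find_first(mdl, ".//sf:meta", ns)
  t_end <- if (!inherits(meta, "xml_missing")) {
    as.numeric(xml2::xml_attr(meta, "t_end"))
  } else 100
  notes <- if (!inherits(meta, "xml_missing")) {
    nt <- xml2::xml_attr(meta, "notes")
    if (is.na(nt)) character() else nt
  } else character()

  comps <- lapply(xml2::xml_find_all(mdl, ".//s:compartment", ns),
                  function(x) {
    kind <- xml2::xml_attr(x, "kind")
    compartment(xml2::xml_attr(x, "id"), xml2::xml_attr(x, "name"),
                if (is.na(kind)) "other" else kind)
  })
  tags <- list()
  species <- lapply(xml2::xml_find_all(mdl, ".//s:species", ns),
                    function(x) {
    id <- xml2::xml_attr(x, "id")
    pws <- xml2::xml_text(xml2::xml_find_all(x, ".//sf:pathway", ns))
    if (length(pws)) tags[[id]] <<- pws
    species_state(id, xml2::xml_attr(x, "name"),
                  xml2::xml_attr(x, "compartment"),
                  as.numeric(xml2::xml_attr(x, "initialAmount")),
                  boundary = identical(xml2::xml_attr(x,
                    "boundaryCondition"), "true"))
  })
  reactions <- lapply(xml2::xml_find_all(mdl, ".//s:reaction", ns),
                      function(x) {
    id <- xml2::xml_attr(x, "id")
    refs <- function(xp) {
      nodes <- xml2::xml_find_all(x, xp, ns)
      stats::setNames(as.integer(round(as.numeric(
        xml2::xml_attr(nodes, "stoichiometry")))),
        xml2::xml_attr(nodes, "species"))
    }
    re <- refs(".//s:listOfReactants/s:speciesReference")
    pr <- refs(".//s:listOfProducts/s:speciesReference")
    mo <- xml2::xml_attr(xml2::xml_find_all(
      x, ".//s:modifierSpeciesReference", ns), "species")
    lp <- xml2::xml_find_all(x, ".//s:localParameter", ns)
    pv <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                          xml2::xml_attr(lp, "id"))
    kind <- if (setequal(names(pv), "k")) "mass_action"
      else if (setequal(names(pv), c("Vmax", "Km"))) "michaelis_menten"
      else if (setequal(names(pv), c("Vmax", "K", "n"))) "hill"
      else stop(sprintf(
        "unsupported kinetic-law construct in reaction '%s' (parameters: %s)",
        id, paste(names(pv), collapse = ", ")), call. = FALSE)
    rl <- switch(kind,
      mass_action = rate_law("mass_action", k = pv[["k"]]),
      michaelis_menten = rate_law("michaelis_menten", Vmax = pv[["Vmax"]],
                                  Km = pv[["Km"]]),
      hill = rate_law("hill", Vmax = pv[["Vmax"]], K = pv[["K"]],
                      n = pv[["n"]]))
    reaction(id, xml2::xml_attr(x, "name"), reactants = re,
             products = pr, modifiers = mo, rate = rl,
             reversible = identical(xml2::xml_attr(x, "reversible"),
                                    "true"))
  })
  reaction_model(comps, species, reactions, pathway_tags = tags,
                 name = xml2::xml_attr(mdl, "name"), t_end = t_end,
                 notes = notes)
}
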