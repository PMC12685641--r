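# End-to-end pipeline: run every analysis stage on a model and emit the
# tables, the hub report and a single JSON manifest of headline numbers.

#' Run the full analysis pipeline
#'
#' Simulation, forward sensitivities, PCA ranking, flux table,
#' quasi-potential reduction, interaction network with topology summary
#' and centralities, hub frequency, and crosstalk scores. All outputs are
#' written as CSV/JSON under `out_dir` (when given) and returned
#' invisibly; the manifest collects the headline numbers. Deterministic
#' given `seed` (which drives the edge-percolation centrality).
#'
#' @param model A `reaction_model`; default is the curated NSCLC model.
#' @param out_dir Output directory, created if needed; `NULL` skips
#'   writing.
#' @param seed Integer seed for the stochastic centrality stage.
#' @param t_end Simulation horizon in seconds.
#' @param flux_min High-flux threshold for the filtered flux table.
#' @param pca_band Two-element numeric, the key-species score band.
#' @param top_k Top-list size per centrality metric for hub frequency.
#' @return (Invisibly) a list with every stage's result and `manifest`.
#' @export
run_pipeline <- function(model = build_nsclc_model(), out_dir = NULL,
                         seed = 1, t_end = model$metadata$t_end,
                         flux_min = 500, pca_band = c(0.8, 1.2),
                         top_k = 20) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  tr   <- stage("simulate", simulate_model(model, t_end = t_end))
  sens <- stage("sensitivity", local_sensitivities(model, t_end = t_end))
  A    <- stage("aggregate", aggregate_sensitivities(sens))
  pca  <- stage("pca", run_pca(A))
  key  <- stage("pca", select_key_species(pca, pca_band[1], pca_band[2]))
  fx   <- stage("flux", compute_fluxes(model, tr))
  fx_top <- stage("flux", top_reactions(fx, flux_min))
  Apar <- A[, !grepl("^x0\\.", colnames(A)), drop = FALSE]
  land <- stage("reduce", quasi_potential_landscape(model, Apar, fx, tr))
  red  <- stage("reduce", reduce_model(model, landscape = land))
  net  <- stage("network", model_to_network(model))
  topo <- stage("network", topology_summary(net))
  cent <- stage("network", centrality_table(net, epc_seed = seed))
  hub  <- stage("network", hub_frequency(cent, k = top_k))
  xt   <- stage("crosstalk", {
    ann <- model$pathway_tags
    if (length(ann) == 0) {
      # unannotated models score zero crosstalk by construction
      ann <- stats::setNames(rep(list("unassigned"), length(net$nodes)),
                             net$nodes)
    }
    crosstalk_scores(net, ann)
  })

  manifest <- list(
    model = model$metadata$name,
    compartments = length(model$compartments),
    species = n_species(model),
    reactions = length(model$reactions),
    t_end = t_end,
    seed = seed,
    key_species = length(key),
    top_flux_count = nrow(fx_top),
    reduction_percent = round(red$reduction_percent),
    retained_reactions = length(red$retained),
    crosstalk_points = sum(xt > 0),
    network = topo,
    max_hub_frequency = max(hub$frequency),
    top_hubs = hub$node[hub$frequency == max(hub$frequency)])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                          row.names = FALSE)
    w(trajectory_frame(tr), "trajectory.csv")
    w(data.frame(species = names(pca$species_score),
                 score = unname(pca$species_score)), "pca_scores.csv")
    jsonlite::write_json(key, file.path(out_dir, "key_species.json"))
    w(fx, "flux_table.csv")
    w(fx_top, "flux_table_top.csv")
    w(land, "landscape.csv")
    jsonlite::write_json(list(retained = red$retained,
                              removed = red$removed,
                              reduction_percent = red$reduction_percent),
                         file.path(out_dir, "reduction.json"),
                         auto_unbox = TRUE, digits = NA)
    w(network_edges(net), "network_edges.csv")
    w(cent, "centrality.csv")
    w(hub, "hub_frequency.csv")
    w(data.frame(node = names(xt), score = unname(xt)), "crosstalk.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(trajectory = tr, sensitivities = sens, scores = A,
                 pca = pca, key_species = key, fluxes = fx,
                 top_fluxes = fx_top, landscape = land, reduction = red,
                 network = net, topology = topo, centrality = cent,
                 hubs = hub, crosstalk = xt, manifest = manifest))
}
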