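test_that("the curated model is clean and carries the printed reactions", {
  m <- build_nsclc_model()
  f <- validate_model(m)
  expect_identical(nrow(f[f$level == "error", ]), 0L)
  # every reaction of the published high-flux table exists verbatim
  expect_true(all(published_flux_table()$name %in% reaction_names(m)))
  # gene loci and external pools are boundary templates
  bt <- species_table(m)
  expect_identical(sum(bt$boundary), 17L)
  expect_true(all(bt$initial_amount[!bt$boundary] >= 1e3 &
                  bt$initial_amount[!bt$boundary] <= 1e6))
  # construction is deterministic
  expect_identical(build_nsclc_model(), m)
})

test_that("late accumulators reproduce the expected autophagy signature", {
  a <- curated_artifacts()
  top6 <- names(net_increase(a$trajectory))[1:6]
  expect_true(all(c("autophagosome", "foxo1_nuc", "foxo3_nuc") %in% top6))
  # ER-membrane cGAMP-STING is a dominant accumulator as well
  expect_true("cgampsting_er" %in% top6)
})

test_that("PCA key-species band holds the energy-sensing components", {
  a <- curated_artifacts()
  p <- run_pca(a$scores)
  sel <- select_key_species(p)
  expect_true(all(c("ulk1c", "adp_cyt") %in% sel))
  expect_true(length(sel) >= 10)
})

test_that("the landscape apex contains the autophagosome-forming reaction", {
  a <- curated_artifacts()
  ord <- a$landscape$reaction[order(a$landscape$combined_rank,
                                    a$landscape$reaction)]
  r19 <- a$model$reactions[[which(reaction_ids(a$model) == "r19")]]
  expect_identical(r19$name, "LC3/ATG12/5/16L -> Autophagosome")
  expect_true("r19" %in% ord[1:12])
})

test_that("hub frequency peaks at the published bridging proteins", {
  a <- curated_artifacts()
  ct <- centrality_table(a$network, epc_seed = 1)
  hub <- hub_frequency(ct, k = 20)
  top <- hub$node[hub$frequency == max(hub$frequency)]
  expect_true(all(c("phagophore", "stat3_dimer") %in% top))
})

test_that("the pipeline manifest is reproducible and complete", {
  a <- curated_artifacts()
  out <- withr::local_tempdir()
  res <- run_pipeline(a$model, out_dir = out, seed = 1)
  mf <- res$manifest
  expect_identical(mf$species, 72L)
  expect_identical(mf$reactions, 83L)
  expect_identical(mf$crosstalk_points, 6L)
  expect_true(file.exists(file.path(out, "manifest.json")))
  mf_disk <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(mf_disk$reduction_percent, 86L)
  expect_identical(sort(unlist(mf_disk$top_hubs)), sort(mf$top_hubs))
})

test_that("pipeline runs are reproducible on a seeded synthetic model", {
  m <- random_model(generator_spec(n_species = 8, n_reactions = 10,
                                   seed = 19))
  r1 <- run_pipeline(m, seed = 4, t_end = 10)
  r2 <- run_pipeline(m, seed = 4, t_end = 10)
  expect_identical(r1$manifest, r2$manifest)
  expect_equal(r1$centrality, r2$centrality)
})
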