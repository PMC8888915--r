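test_that("simulation is bit-identical under a fixed seed", {
  cfg <- scenario_preset("tiny_fixture", seed = 7)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(unclass(s1$counts), unclass(s2$counts))
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$tree$edge.length, s2$tree$edge.length)
  expect_identical(s1$guilds, s2$guilds)
  s3 <- simulate_community(scenario_preset("tiny_fixture", seed = 8))
  expect_false(identical(unclass(s1$counts), unclass(s3$counts)))
})

test_that("inconsistent configurations are rejected", {
  strata <- data.frame(land_use = "grassland", location = "none",
                       n_samples = 6)
  expect_error(simulation_config(
    n_taxa = 5, strata = strata,
    modules = list(list(taxon_count = 10, loading = 0.9,
                        stratum = "grassland"))), "n_taxa")
  expect_error(simulation_config(
    n_taxa = 20, strata = strata,
    modules = list(list(taxon_count = 4, loading = 1.5,
                        stratum = "grassland"))), "loadings")
  expect_error(simulation_config(
    n_taxa = 20, strata = strata,
    indicators = list(list(combo = "mars", lfc = 2))), "unknown stratum")
  expect_error(simulation_config(
    n_taxa = 20, strata = strata,
    guild_fractions = c(a = 0.7, b = 0.6)), "sum")
  expect_error(scenario_preset("no_such_preset"), "available")
})

test_that("presets encode the intended study designs", {
  ob <- scenario_preset("orchard_benchmark", seed = 1)
  expect_equal(nrow(ob$strata), 5L)
  expect_equal(sum(ob$strata$n_samples), 450L)
  expect_equal(length(ob$hubs), 10L)
  nc <- scenario_preset("null_community", seed = 1)
  expect_equal(length(nc$modules), 0L)
  expect_equal(length(nc$hubs), 0L)
  expect_equal(length(nc$indicators), 0L)
  tf <- scenario_preset("tiny_fixture", seed = 1)
  expect_lte(tf$n_taxa, 12L)
  expect_lte(sum(tf$strata$n_samples), 10L)
})

test_that("planted indicator taxa separate their strata by construction", {
  sim <- simulate_community(scenario_preset("tiny_fixture", seed = 4))
  strata <- stratum_labels(sim$metadata)
  rel <- sweep(unclass(sim$counts), 2, sample_depths(sim$counts), "/")
  for (i in seq_len(nrow(sim$truth$indicators))) {
    tx <- sim$truth$indicators$taxon_id[i]
    cmb <- strsplit(sim$truth$indicators$combo[i], "+", fixed = TRUE)[[1]]
    inside <- mean(rel[tx, strata %in% cmb])
    outside <- mean(rel[tx, !strata %in% cmb])
    expect_gt(inside, outside)
  }
})

test_that("planted modules produce super-threshold rank correlations", {
  hits <- vapply(1:5, function(s) {
    cfg <- simulation_config(
      n_taxa = 30,
      strata = data.frame(land_use = "grassland", location = "none",
                          n_samples = 90),
      modules = list(list(taxon_count = 6, loading = 0.95,
                          stratum = "grassland")),
      depth_mean = 10000, depth_sd = 0.1, seed = s
    )
    sim <- simulate_community(cfg)
    sm <- suppressWarnings(spearman_matrix(sim$counts))
    mt <- sim$truth$groups[[1]]$taxa
    within <- sm$rho[mt, mt][upper.tri(diag(length(mt)))]
    all(within > 0.6)
  }, logical(1))
  expect_true(all(hits))
})

test_that("stronger overdispersion never strengthens planted correlations", {
  mean_rho <- function(conc, seed = 3) {
    cfg <- simulation_config(
      n_taxa = 30,
      strata = data.frame(land_use = "grassland", location = "none",
                          n_samples = 90),
      modules = list(list(taxon_count = 6, loading = 0.95,
                          stratum = "grassland")),
      depth_mean = 10000, depth_sd = 0.1, overdispersion = conc, seed = seed
    )
    sim <- simulate_community(cfg)
    sm <- suppressWarnings(spearman_matrix(sim$counts))
    mt <- sim$truth$groups[[1]]$taxa
    mean(sm$rho[mt, mt][upper.tri(diag(length(mt)))])
  }
  # concentration DOWN = overdispersion UP = degraded correlation
  for (s in 1:3) {
    expect_gte(mean_rho(10000, s), mean_rho(50, s))
  }
})

test_that("null communities yield almost no super-threshold edges", {
  edges <- vapply(1:10, function(s) {
    sim <- simulate_community(scenario_preset("null_community", seed = s))
    sm <- suppressWarnings(spearman_matrix(sim$counts))
    nrow(build_network(sm)$edges)
  }, numeric(1))
  n_pairs <- choose(40, 2)
  expect_lt(mean(edges), 0.01 * n_pairs)
})

test_that("simulations serialize to the plain-text artifact set", {
  sim <- simulate_community(scenario_preset("tiny_fixture", seed = 2))
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  expect_true(all(file.exists(paths)))
  back <- read_count_table(paths["counts"])
  expect_identical(unclass(back), unclass(sim$counts))
  truth <- jsonlite::read_json(paths["ground_truth"])
  expect_equal(length(truth$indicators), 2L) # one row object per indicator
})
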