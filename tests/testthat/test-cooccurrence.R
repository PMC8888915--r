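test_that("Spearman rho and t-approximation p match hand calculations", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 3, 2, 5, 4),
             c = c(5, 4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:5)
  sm <- spearman_matrix(count_matrix(m))
  # perfect reversal
  expect_equal(sm$rho["a", "c"], -1)
  expect_equal(sm$p["a", "c"], 0)
  # classical d^2 formula: 1 - 6*4/120 = 0.8, p from t = 2.3094 on 3 df
  expect_equal(sm$rho["a", "b"], 0.8)
  expect_equal(sm$p["a", "b"], 0.104, tolerance = 0.002)
  expect_true(isSymmetric(sm$rho) && isSymmetric(sm$p))
  expect_equal(unname(diag(sm$rho)), rep(1, 3))
})

test_that("constant taxa are excluded and tiny designs rejected", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(4, 4, 4, 4), c = c(2, 1, 4, 3))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(sm <- spearman_matrix(count_matrix(m)), "zero-variance")
  expect_setequal(sm$taxon_ids, c("a", "c"))
  expect_error(spearman_matrix(count_matrix(m[, 1:3])), "at least 4")
})

test_that("exact Spearman p agrees with the t approximation direction", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 3, 2, 5, 4)
  p_exact <- spearman_p_exact(x, y)
  # exact two-sided null probability of |rho| >= 0.8 at n = 5: 16/120
  expect_equal(p_exact, 2 / 15, tolerance = 1e-10)
})

test_that("network construction applies strict thresholds", {
  ids <- c("a", "b", "c")
  rho <- matrix(1, 3, 3, dimnames = list(ids, ids))
  p <- matrix(0, 3, 3, dimnames = list(ids, ids))
  rho["a", "b"] <- rho["b", "a"] <- 0.9;  p["a", "b"] <- p["b", "a"] <- 0.001
  rho["a", "c"] <- rho["c", "a"] <- 0.61; p["a", "c"] <- p["c", "a"] <- 0.01
  rho["b", "c"] <- rho["c", "b"] <- 0.59; p["b", "c"] <- p["c", "b"] <- 0.001
  corr <- corr_from(rho, p)
  net <- build_network(corr)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(length(net$taxon_ids), 3L)

  # rho exactly at the threshold yields no edge (strict >)
  rho["a", "c"] <- rho["c", "a"] <- 0.6
  expect_equal(nrow(build_network(corr_from(rho, p))$edges), 1L)

  # the significance gate alone removes everything, nodes unchanged
  p_all <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(p_all) <- 0
  net0 <- build_network(corr_from(rho, p_all))
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(length(net0$taxon_ids), 3L)

  # negative correlations are excluded unless positive_only is dropped
  # (rho: ab=-0.9, ac=0.6, bc=0.59; all p < 0.05)
  rho["a", "b"] <- rho["b", "a"] <- -0.9
  expect_equal(nrow(build_network(corr_from(rho, p), rho_min = -1)$edges), 2L)
  expect_equal(nrow(build_network(corr_from(rho, p), rho_min = -1,
                                  positive_only = FALSE)$edges), 3L)

  expect_error(build_network(corr, rho_min = 1.5), "rho_min")
  expect_error(build_network(corr, alpha = 0), "alpha")
})

test_that("filtering is monotone: tighter thresholds never add edges", {
  set.seed(5)
  ids <- paste0("t", 1:8)
  r <- matrix(runif(64, -1, 1), 8, 8, dimnames = list(ids, ids))
  r <- (r + t(r)) / 2; diag(r) <- 1
  pv <- matrix(runif(64), 8, 8, dimnames = list(ids, ids))
  pv <- (pv + t(pv)) / 2; diag(pv) <- 0
  corr <- corr_from(r, pv)
  for (i in 1:20) {
    rho1 <- runif(1, 0, 0.9); rho2 <- runif(1, rho1, 1)
    a1 <- runif(1, 0.01, 1); a2 <- runif(1, 0.001, a1)
    loose <- build_network(corr, rho_min = rho1, alpha = a1)
    tight_rho <- build_network(corr, rho_min = rho2, alpha = a1)
    tight_a <- build_network(corr, rho_min = rho1, alpha = a2)
    key <- function(n) paste(n$edges$source, n$edges$target)
    expect_true(all(key(tight_rho) %in% key(loose)))
    expect_true(all(key(tight_a) %in% key(loose)))
  }
})

test_that("topology metrics match closed forms on canonical graphs", {
  # triangle: complete graph
  adj <- matrix(1L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(adj) <- 0L
  tri <- net_from_adj(adj)
  cent <- node_centrality(tri)
  expect_equal(cent$degree, rep(2, 3))
  expect_equal(cent$closeness, rep(0.5, 3))
  expect_equal(cent$betweenness, rep(0, 3))
  topo <- topology_summary(tri)
  expect_equal(topo$diameter, 1)
  expect_equal(topo$avg_path_length, 1)
  expect_equal(topo$mean_degree, 2)
  expect_equal(topo$n_components, 1L)

  # path a-b-c
  adj2 <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  adj2[1, 2] <- adj2[2, 1] <- adj2[2, 3] <- adj2[3, 2] <- 1L
  pth <- net_from_adj(adj2)
  cent2 <- node_centrality(pth)
  expect_equal(cent2$betweenness[cent2$taxon_id == "b"], 1)
  expect_equal(cent2$closeness[cent2$taxon_id == "b"], 0.5)
  expect_equal(cent2$closeness[cent2$taxon_id == "a"], 1 / 3)
  topo2 <- topology_summary(pth)
  expect_equal(topo2$diameter, 2)
  expect_equal(topo2$avg_path_length, 4 / 3)
})

test_that("edgeless graphs report undefined path metrics, not zero", {
  adj <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  topo <- topology_summary(net_from_adj(adj))
  expect_true(is.na(topo$diameter))
  expect_true(is.na(topo$avg_path_length))
  expect_true(is.na(topo$modularity))
  expect_equal(topo$n_components, 3L)
  cent <- node_centrality(net_from_adj(adj))
  expect_equal(cent$closeness, rep(0, 3))
})

test_that("modularity equals Newman's formula on the returned partition", {
  adj <- barbell_adj()
  topo <- topology_summary(net_from_adj(adj))
  membership <- attr(topo, "membership")
  idx <- match(rownames(adj), names(membership))
  expect_equal(topo$modularity,
               bf_modularity(adj, as.integer(membership[idx])))
  expect_equal(topo$modularity, 5 / 14)
})

test_that("keystone selection uses strict joint thresholds", {
  crit <- keystone_criteria("fungi")
  fake_net <- net_from_adj(matrix(0L, 3, 3,
                                  dimnames = list(letters[1:3], letters[1:3])))
  cent <- data.frame(taxon_id = c("a", "b", "c"),
                     degree = c(6, 5, 7),
                     closeness = c(0.006, 0.006, 0.004),
                     betweenness = c(30, 30, 30))
  expect_equal(identify_keystones(fake_net, crit, centrality = cent), "a")
  # degree exactly 5 fails the strict inequality
  cent$degree <- c(5, 5, 5)
  expect_equal(identify_keystones(fake_net, crit, centrality = cent),
               character(0))
  # empty network -> no keystones
  expect_equal(identify_keystones(fake_net, crit), character(0))
  expect_error(keystone_criteria(degree_min = 5), "criteria")
  bact <- keystone_criteria("bacteria")
  expect_equal(c(bact$degree_min, bact$closeness_min, bact$betweenness_max),
               c(15, 0.03, 50))
})

test_that("per-stratum networks partition samples correctly", {
  set.seed(21)
  sim <- simulate_community(scenario_preset("tiny_fixture", seed = 3))
  nets <- suppressWarnings(per_stratum_networks(sim$counts, sim$metadata))
  expect_named(nets, c("IPM_drive_row", "grassland"))
  expect_equal(nets$grassland$stratum, "grassland")

  # single stratum equals build_network on the full matrix
  gl <- sim$metadata$sample_id[sim$metadata$land_use == "grassland"]
  sub <- count_matrix(unclass(sim$counts)[, gl])
  direct <- suppressWarnings(build_network(spearman_matrix(sub)))
  expect_equal(nets$grassland$edges, direct$edges)

  # unmapped sample and undersized strata are errors
  md_bad <- sim$metadata[-1, ]
  expect_error(suppressWarnings(per_stratum_networks(sim$counts, md_bad)),
               "missing from metadata|without a stratum")
  strata <- stratum_labels(sim$metadata)
  strata[strata == "grassland"][1:3] <- NA
  strata_small <- strata[!is.na(strata)]
  expect_error(
    suppressWarnings(per_stratum_networks(
      count_matrix(unclass(sim$counts)[, names(strata_small)]),
      sim$metadata, strata = strata_small)),
    "fewer than"
  )
})

test_that("edge sets are invariant to sample and taxon order", {
  set.seed(77)
  m <- matrix(rpois(10 * 20, 20), 10, 20,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:20)))
  m[1, ] <- m[2, ] + rpois(20, 2) # one strongly correlated pair
  net1 <- suppressWarnings(build_network(spearman_matrix(count_matrix(m)),
                                         rho_min = 0.3))
  perm_s <- sample(20); perm_t <- sample(10)
  net2 <- suppressWarnings(build_network(
    spearman_matrix(count_matrix(m[perm_t, perm_s])), rho_min = 0.3))
  expect_equal(net1$edges[c("source", "target")],
               net2$edges[c("source", "target")])
  expect_equal(net1$edges$rho, net2$edges$rho, tolerance = 1e-12)
})
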