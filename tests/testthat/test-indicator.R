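test_that("the group-equalized statistic matches hand computation", {
  a <- c(5, 6, 7, 0, 1, 2)
  strata <- rep(c("g1", "g2"), each = 3)
  # equal groups: r.g reduces to the plain point-biserial 7.5/sqrt(41.5*1.5)
  expect_equal(rg_statistic(a, "g1", strata), 0.9506, tolerance = 1e-3)
  expect_equal(rg_statistic(a, "g1", strata),
               7.5 / sqrt(41.5 * 1.5), tolerance = 1e-12)
  # indicator negation flips the sign
  expect_equal(rg_statistic(a, "g2", strata), -rg_statistic(a, "g1", strata))
  # zero variance is undefined
  expect_warning(r <- rg_statistic(rep(3, 6), "g1", strata), "zero-variance")
  expect_true(is.na(r))
  expect_error(rg_statistic(a, "nope", strata), "unknown stratum")
})

test_that("with equal group sizes r.g equals plain Pearson point-biserial", {
  set.seed(14)
  strata <- rep(c("g1", "g2", "g3"), each = 7)
  for (i in 1:20) {
    a <- rnorm(21)
    cmb <- sample(c("g1", "g2", "g3"), sample(1:2, 1))
    ind <- as.numeric(strata %in% cmb)
    expect_equal(rg_statistic(a, cmb, strata), cor(a, ind),
                 tolerance = 1e-12)
  }
})

test_that("group equalization removes group-size bias", {
  # unequal groups: equalized statistic equals the statistic on balanced
  # duplication of the smaller group (oracle by construction)
  a <- c(5, 9, 2, 1, 1, 7, 2)
  strata <- c("g1", "g1", "g1", "g2", "g2", "g2", "g2")
  # weighting each g1 site 4x and each g2 site 3x balances the groups, so
  # the equalized statistic must equal plain Pearson on that duplication
  a_bal <- c(rep(a[1:3], 4), rep(a[4:7], 3))
  strata_bal <- c(rep("g1", 12), rep("g2", 12))
  r_g <- rg_statistic(a, "g1", strata)
  r_bal <- cor(a_bal, as.numeric(strata_bal == "g1"))
  expect_equal(r_g, r_bal, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r_g, cor(a, as.numeric(strata == "g1")),
                                tolerance = 1e-7)))
})

test_that("best_combination searches all proper subsets with tie-breaks", {
  strata3 <- rep(c("g1", "g2", "g3"), each = 4)
  # planted maximum in g1
  a <- c(9, 10, 11, 10, 1, 0, 2, 1, 1, 2, 0, 1)
  expect_equal(best_combination(a, strata3)$combo, "g1")
  # equally abundant in g1 and g2, absent in g3 -> the pair wins
  a2 <- c(5, 6, 5, 6, 5, 6, 5, 6, 0, 0, 0, 0)
  expect_equal(best_combination(a2, strata3)$combo, c("g1", "g2"))
  # K = 5 -> 2^5 - 2 = 30 combinations evaluated
  strata5 <- rep(paste0("g", 1:5), each = 2)
  res <- best_combination(rnorm(10), strata5)
  expect_equal(res$n_combos, 30L)
  expect_error(best_combination(rnorm(4), rep("g1", 4)), "at least 2 strata")
})

test_that("permutation p-values hit the formula floor and are deterministic", {
  strata <- rep(c("g1", "g2", "g3"), each = 10)
  a <- c(rnorm(10, 10), rnorm(20, 0)) # overwhelming g1 signal
  res <- permutation_test(a, strata, n_perm = 999, seed = 5)
  expect_equal(res$p_value, 1 / 1000) # observed beats all permutations
  expect_equal(res$combo, "g1")
  res99 <- permutation_test(a, strata, n_perm = 99, seed = 5)
  expect_equal(res99$p_value, 0.01)
  expect_error(permutation_test(a, strata, n_perm = 50, seed = 1), "99")
  # fixed seed -> identical p; different seed -> same decision, close p
  set.seed(8)
  b <- rnorm(30) + as.numeric(strata == "g2")
  r1 <- permutation_test(b, strata, n_perm = 199, seed = 3)
  r2 <- permutation_test(b, strata, n_perm = 199, seed = 3)
  expect_identical(r1, r2)
})

test_that("p-values are invariant to affine transforms of abundance", {
  # a positive affine map transforms every combo statistic identically,
  # so the permutation rank (hence p) is unchanged
  strata <- rep(c("g1", "g2"), each = 8)
  set.seed(19)
  a <- rnorm(16) + 0.8 * (strata == "g1")
  r1 <- permutation_test(a, strata, n_perm = 199, seed = 11)
  r2 <- permutation_test(3 * a + 7, strata, n_perm = 199, seed = 11)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$combo, r2$combo)
  expect_equal(r1$observed, r2$observed, tolerance = 1e-12)
})

test_that("indicator_analysis tabulates taxa and skips constants", {
  set.seed(23)
  m <- rbind(
    up_in_g1 = c(rpois(6, 50), rpois(6, 5)),
    flat = rpois(12, 20),
    constant = rep(7L, 12)
  )
  colnames(m) <- paste0("s", 1:12)
  strata <- setNames(rep(c("g1", "g2"), each = 6), colnames(m))
  expect_warning(
    tab <- indicator_analysis(count_matrix(m), strata, n_perm = 199, seed = 2),
    "zero-variance"
  )
  expect_equal(nrow(tab), 2L)
  row1 <- tab[tab$taxon_id == "up_in_g1", ]
  expect_equal(row1$best_combo, "g1")
  expect_lt(row1$p_value, 0.05)
  expect_true(all(tab$p_value >= 1 / 200))
})

test_that("the bipartite association network thresholds and summarizes", {
  tab <- data.frame(
    taxon_id = c("t1", "t2"),
    best_combo = c("g1", "g1+g2"),
    stat = c(0.9, 0.5), p_value = c(0.01, 0.2), n_perm = 999L
  )
  an <- association_network(tab, alpha = 0.05)
  expect_equal(an$n_significant, 1L)
  expect_equal(igraph::ecount(an$graph), 1L)
  taxa_nodes <- igraph::V(an$graph)$name[!igraph::V(an$graph)$type]
  expect_equal(taxa_nodes, "t1")

  # all nonsignificant -> empty graph
  tab$p_value <- c(0.5, 0.9)
  an0 <- association_network(tab)
  expect_equal(an0$n_significant, 0L)
  expect_equal(igraph::ecount(an0$graph), 0L)

  # specialist fraction is the share of cardinality-1 combos
  tab2 <- data.frame(
    taxon_id = paste0("t", 1:10),
    best_combo = c(rep("g1", 4), rep("g2", 2), rep("g1+g2", 4)),
    stat = 0.8, p_value = 0.001, n_perm = 999L
  )
  an2 <- association_network(tab2)
  expect_equal(an2$specialist_fraction, 0.6)
  expect_equal(an2$shared_pairs$n_taxa[an2$shared_pairs$stratum_a == "g1"], 4L)
})
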