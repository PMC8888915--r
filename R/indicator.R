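# Correlation-based indicator (association) analysis: group-equalized
# point-biserial statistic, exhaustive combination search over strata,
# whole-sample label permutation null.

# site weights making each stratum contribute total weight N/K
equalized_weights <- function(site_strata, equalize = TRUE) {
  site_strata <- as.character(site_strata)
  n <- length(site_strata)
  if (!equalize) return(rep(1, n))
  sizes <- table(site_strata)
  k <- length(sizes)
  (n / k) / as.numeric(sizes[site_strata])
}

# weighted Pearson correlation between abundance and a 0/1 indicator
weighted_pointbiserial <- function(abundance, indicator, w) {
  sw <- sum(w)
  ma <- sum(w * abundance) / sw
  mc <- sum(w * indicator) / sw
  va <- sum(w * (abundance - ma)^2)
  vc <- sum(w * (indicator - mc)^2)
  if (va <= 0 || vc <= 0) return(NA_real_)
  sum(w * (abundance - ma) * (indicator - mc)) / sqrt(va * vc)
}

#' Group-equalized point-biserial association statistic (r.g)
#'
#' Pearson correlation between a taxon's abundance and the 0/1 membership
#' indicator of a stratum combination, computed after reweighting sites so
#' each stratum contributes equal total weight N/K. With equal stratum
#' sizes this reduces to the plain point-biserial correlation; with unequal
#' sizes the equalization removes group-size bias. `equalize = FALSE` gives
#' the plain (unweighted) statistic.
#'
#' @param abundance numeric abundance vector over N sites (rarefied counts).
#' @param combo character vector: the stratum combination being tested.
#' @param site_strata stratum label of each site.
#' @param equalize use group-equalized weights (default TRUE).
#' @return correlation in \[-1, 1\]; NA (with a warning) when the abundance
#'   has zero variance.
#' @export
rg_statistic <- function(abundance, combo, site_strata, equalize = TRUE) {
  site_strata <- as.character(site_strata)
  if (length(abundance) != length(site_strata)) {
    abort("abundance and site_strata lengths differ")
  }
  if (length(abundance) < 2L) abort("need at least 2 sites")
  if (stats::var(abundance) == 0) {
    warn("zero-variance abundance: statistic undefined")
    return(NA_real_)
  }
  strata <- sort(unique(site_strata))
  bad <- setdiff(combo, strata)
  if (length(bad)) abort("unknown stratum in combo: %s", paste(bad, collapse = ", "))
  w <- equalized_weights(site_strata, equalize)
  weighted_pointbiserial(abundance, as.numeric(site_strata %in% combo), w)
}

# all nonempty proper subsets of the strata, ordered by size then
# lexicographically - the tie-break order for best_combination()
stratum_combinations <- function(strata) {
  strata <- sort(unique(as.character(strata)))
  k <- length(strata)
  if (k < 2L) abort("need at least 2 strata (got %d)", k)
  out <- list()
  for (size in seq_len(k - 1L)) {
    cmb <- utils::combn(strata, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Best stratum combination for one taxon
#'
#' Evaluates [rg_statistic()] over every nonempty proper subset of the
#' strata (2^K - 2 combinations) and returns the maximizer. Ties are broken
#' toward the smaller combination, then lexicographically.
#'
#' @inheritParams rg_statistic
#' @return list with `combo` (character vector), `stat`, and `n_combos`.
#' @export
best_combination <- function(abundance, site_strata, equalize = TRUE) {
  combos <- stratum_combinations(site_strata)
  w <- equalized_weights(site_strata, equalize)
  if (stats::var(abundance) == 0) {
    warn("zero-variance abundance: statistic undefined")
    return(list(combo = NULL, stat = NA_real_, n_combos = length(combos)))
  }
  stats_ <- vapply(combos, function(cmb) {
    weighted_pointbiserial(abundance,
                           as.numeric(as.character(site_strata) %in% cmb), w)
  }, numeric(1))
  best <- max(stats_)
  pick <- which(stats_ >= best - 1e-12)[1L] # list pre-ordered for tie-breaks
  list(combo = combos[[pick]], stat = stats_[pick], n_combos = length(combos))
}

# indicator design matrices shared by the permutation machinery:
# C: N x m 0/1 combo membership; precomputed weighted moments of each combo
combo_design <- function(site_strata, equalize = TRUE) {
  combos <- stratum_combinations(site_strata)
  s <- as.character(site_strata)
  C <- vapply(combos, function(cmb) as.numeric(s %in% cmb),
              numeric(length(s)))
  w <- equalized_weights(site_strata, equalize)
  sw <- sum(w)
  wc <- w * C                      # N x m
  swc <- colSums(wc)               # sum w c
  vc <- colSums(wc * C) - swc^2 / sw
  list(combos = combos, C = C, w = w, sw = sw, wc = wc, swc = swc, vc = vc)
}

# maximized r.g over combos for each row of an abundance matrix A (q x N)
max_stat_rows <- function(A, d) {
  s1 <- A %*% d$w              # q x 1: sum w a
  s2 <- (A * A) %*% d$w        # q x 1: sum w a^2
  va <- as.numeric(s2 - s1^2 / d$sw)
  cov <- A %*% d$wc - tcrossprod(as.numeric(s1), d$swc / d$sw) # q x m
  denom <- sqrt(pmax(va, 0) %o% pmax(d$vc, 0))
  r <- cov / denom
  r[!is.finite(r)] <- -Inf
  apply(r, 1L, max)
}

#' Permutation test for an indicator association
#'
#' Permutes site labels as whole samples; at each permutation the statistic
#' maximized over all stratum combinations is recomputed, and
#' p = (1 + #\{perm >= observed\}) / (n_perm + 1). Maximizing inside the null
#' accounts for the combination search, so the p-value is valid for the
#' selected combination. Deterministic under a fixed seed.
#'
#' @inheritParams rg_statistic
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer RNG seed.
#' @return list with `p_value`, `observed` (the maximized statistic),
#'   `combo` (its maximizer) and `n_perm`.
#' @export
permutation_test <- function(abundance, site_strata, n_perm = 999L,
                             seed = 1L, equalize = TRUE) {
  if (n_perm < 99L) abort("n_perm must be at least 99")
  if (stats::var(abundance) == 0) {
    warn("zero-variance abundance: statistic undefined")
    return(list(p_value = NA_real_, observed = NA_real_, combo = NULL,
                n_perm = as.integer(n_perm)))
  }
  d <- combo_design(site_strata, equalize)
  obs <- best_combination(abundance, site_strata, equalize)
  n <- length(abundance)
  perm_max <- with_seed(seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    # permuting abundances against fixed labels == permuting labels
    A <- matrix(abundance[idx], nrow = n_perm, ncol = n, byrow = TRUE)
    max_stat_rows(A, d)
  })
  p <- (1 + sum(perm_max >= obs$stat - 1e-12)) / (n_perm + 1)
  list(p_value = p, observed = obs$stat, combo = obs$combo,
       n_perm = as.integer(n_perm))
}

#' Indicator analysis of every taxon in a count matrix
#'
#' For each taxon: finds the best stratum combination by exhaustive search,
#' then assigns a permutation p-value with the combination search repeated
#' inside the null. Zero-variance taxa are skipped with a warning.
#'
#' @param x a [count_matrix] (typically rarefied).
#' @param site_strata stratum label per sample (named by sample_id, e.g.
#'   from [stratum_labels()]); reordered to match the matrix columns.
#' @inheritParams permutation_test
#' @return data.frame (class `indicator_table`) with one row per tested
#'   taxon: taxon_id, best_combo (strata joined by "+"), stat, p_value,
#'   n_perm.
#' @export
indicator_analysis <- function(x, site_strata, n_perm = 999L, seed = 1L,
                               equalize = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  if (!is.null(names(site_strata))) {
    missing <- setdiff(sample_ids(x), names(site_strata))
    if (length(missing)) {
      abort("sample(s) without a stratum: %s", paste(missing, collapse = ", "))
    }
    site_strata <- site_strata[sample_ids(x)]
  } else if (length(site_strata) != ncol(x)) {
    abort("site_strata length does not match sample count")
  }
  m <- unclass(x)
  variable <- apply(m, 1L, function(v) stats::var(v) > 0)
  if (any(!variable)) {
    warn("skipping %d zero-variance taxa", sum(!variable))
  }
  taxa <- rownames(m)[variable]
  rows <- lapply(taxa, function(t) {
    res <- permutation_test(m[t, ], site_strata, n_perm = n_perm,
                            seed = derive_seed(seed, t), equalize = equalize)
    data.frame(taxon_id = t, best_combo = paste(res$combo, collapse = "+"),
               stat = res$observed, p_value = res$p_value,
               n_perm = res$n_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("indicator_table", class(out))
  out
}

#' Bipartite stratum-taxon association network
#'
#' Links every significantly associated taxon (p < alpha) to each stratum of
#' its best combination; strata are source nodes, taxa target nodes.
#' Summaries report counts per combination cardinality (cardinality 1 =
#' habitat specialists) and the number of taxa shared by each pair of
#' strata.
#'
#' @param table an `indicator_table` from [indicator_analysis()].
#' @param alpha significance threshold (strict <, default 0.05).
#' @return list of class `association_network`: `graph` (bipartite
#'   [igraph]), `n_significant`, `specialist_fraction`, `by_cardinality`
#'   (table), `shared_pairs` (data.frame stratum_a, stratum_b, n_taxa).
#' @export
association_network <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "data.frame"))
  sig <- table[!is.na(table$p_value) & table$p_value < alpha, , drop = FALSE]
  combos <- strsplit(sig$best_combo, "+", fixed = TRUE)
  strata <- sort(unique(unlist(combos)))
  edges <- if (nrow(sig)) {
    do.call(rbind, Map(function(t, cmb) {
      data.frame(source = cmb, target = t, stringsAsFactors = FALSE)
    }, sig$taxon_id, combos))
  } else {
    data.frame(source = character(0), target = character(0))
  }
  verts <- data.frame(
    name = c(strata, sig$taxon_id),
    type = c(rep(TRUE, length(strata)), rep(FALSE, nrow(sig))),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  card <- lengths(combos)
  by_card <- if (length(card)) table(cardinality = card) else
    table(cardinality = integer(0))
  pairs <- if (length(strata) >= 2L && nrow(sig)) {
    pr <- utils::combn(strata, 2L)
    data.frame(
      stratum_a = pr[1L, ], stratum_b = pr[2L, ],
      n_taxa = apply(pr, 2L, function(ab) {
        sum(vapply(combos, function(cmb) all(ab %in% cmb), logical(1)))
      }),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(stratum_a = character(0), stratum_b = character(0),
               n_taxa = integer(0))
  }
  structure(list(
    graph = g,
    n_significant = nrow(sig),
    specialist_fraction = if (nrow(sig)) mean(card == 1L) else NA_real_,
    by_cardinality = by_card,
    shared_pairs = pairs,
    alpha = alpha
  ), class = "association_network")
}
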