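# Co-occurrence networks: Spearman correlation matrices, thresholded
# network construction, topology metrics, keystone taxa.

#' Spearman correlation matrix across samples
#'
#' Rank-correlates every pair of taxa across the samples of a count matrix.
#' rho is the Pearson correlation of mid-ranks (average ranks on ties); the
#' two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom (the
#' standard large-n treatment; an exact enumeration is available via
#' [spearman_p_exact()] for very small n). rho = +/-1 maps to p = 0.
#'
#' Taxa with zero variance across samples cannot be rank-correlated and are
#' excluded with a warning.
#'
#' @param x a [count_matrix] (typically rarefied), or numeric matrix with
#'   taxa as rows.
#' @return object of class `correlation_matrix`: list with `taxon_ids`,
#'   symmetric matrices `rho` and `p`, and `n` (samples used).
#' @export
spearman_matrix <- function(x) {
  m <- if (inherits(x, "count_matrix")) unclass(x) else as.matrix(x)
  n <- ncol(m)
  if (n < 4L) abort("need at least 4 samples for correlation (got %d)", n)
  v <- apply(m, 1L, stats::var)
  constant <- rownames(m)[v == 0]
  if (length(constant)) {
    warn("excluding %d zero-variance taxa from correlation: %s%s",
         length(constant), paste(utils::head(constant, 5L), collapse = ", "),
         if (length(constant) > 5L) ", ..." else "")
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) abort("fewer than 2 taxa with nonzero variance")
  ranks <- t(apply(m, 1L, rank)) # mid-ranks
  rho <- stats::cor(t(ranks))
  rho <- pmin(pmax(rho, -1), 1)
  rho[abs(rho) > 1 - 1e-12] <- sign(rho[abs(rho) > 1 - 1e-12]) # snap +/-1
  p <- spearman_p_t(rho, n)
  diag(rho) <- 1
  diag(p) <- 0
  structure(list(taxon_ids = rownames(m), rho = rho, p = p, n = n,
                 excluded = constant),
            class = "correlation_matrix")
}

# two-sided p via the t approximation; rho = +/-1 -> p = 0
spearman_p_t <- function(rho, n) {
  p <- matrix(0, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  sel <- abs(rho) < 1
  tstat <- rho[sel] * sqrt((n - 2) / (1 - rho[sel]^2))
  p[sel] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

#' Exact permutation p-value for one Spearman correlation
#'
#' Enumerates all n! permutations of one margin (feasible for n <= 8) and
#' returns the two-sided probability of |rho| at least as large as observed.
#'
#' @param x,y numeric vectors of equal length n <= 8.
#' @return two-sided exact p-value.
#' @export
spearman_p_exact <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n > 8L) abort("exact enumeration supported for n <= 8 only (got %d)", n)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  perms <- all_permutations(n)
  vals <- abs(apply(perms, 1L, function(idx) stats::cor(rx, ry[idx])))
  mean(vals >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Build a co-occurrence network from a correlation matrix
#'
#' An edge joins taxa i and j iff rho_ij > rho_min AND p_ij < alpha AND
#' (when `positive_only`) rho_ij > 0 - all inequalities strict, so
#' rho exactly at the threshold yields no edge. Default thresholds
#' rho_min = 0.6, alpha = 0.05. Taxa failing every test remain as isolated
#' nodes. No multiple-testing correction is applied by default (raw p);
#' `adjust = "BH"` switches to Benjamini-Hochberg adjusted p-values.
#'
#' @param corr a `correlation_matrix` from [spearman_matrix()].
#' @param rho_min correlation threshold (strict >), in \[-1, 1\].
#' @param alpha significance threshold (strict <), in (0, 1\].
#' @param positive_only keep only positive correlations (default TRUE).
#' @param stratum optional label attached to the network.
#' @param adjust p-value adjustment method (`"none"` or `"BH"`).
#' @return object of class `cooccurrence_network`: list with `stratum`,
#'   `taxon_ids` (all nodes), `edges` (data.frame source, target, rho, p)
#'   and the thresholds used.
#' @export
build_network <- function(corr, rho_min = 0.6, alpha = 0.05,
                          positive_only = TRUE, stratum = NA_character_,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(corr, "correlation_matrix"))
  if (length(rho_min) != 1L || rho_min < -1 || rho_min > 1) {
    abort("rho_min must lie in [-1, 1]")
  }
  if (length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    abort("alpha must lie in (0, 1]")
  }
  ids <- corr$taxon_ids
  ut <- upper.tri(corr$rho)
  ii <- row(corr$rho)[ut]
  jj <- col(corr$rho)[ut]
  rho <- corr$rho[ut]
  p <- corr$p[ut]
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  keep <- rho > rho_min & p < alpha
  if (positive_only) keep <- keep & rho > 0
  edges <- data.frame(
    source = ids[ii[keep]], target = ids[jj[keep]],
    rho = rho[keep], p = p[keep], stringsAsFactors = FALSE
  )
  # canonical order: sorted endpoints, then lexicographic
  swap <- edges$source > edges$target
  tmp <- edges$source[swap]
  edges$source[swap] <- edges$target[swap]
  edges$target[swap] <- tmp
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(stratum = stratum, taxon_ids = ids, edges = edges,
                 rho_min = rho_min, alpha = alpha, n_samples = corr$n),
            class = "cooccurrence_network")
}

#' @rdname build_network
#' @param network a `cooccurrence_network`.
#' @return `as_igraph()`: the network as an undirected [igraph] graph with
#'   isolated nodes retained and edge attributes rho, p.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cooccurrence_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$taxon_ids))
  g
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network [%s]: %d nodes, %d edges (rho > %g, p < %g)\n",
              x$stratum %||% "?", length(x$taxon_ids), nrow(x$edges),
              x$rho_min, x$alpha))
  invisible(x)
}

#' Node-level centrality of a co-occurrence network
#'
#' Degree; unnormalized closeness 1 / sum of shortest-path distances to the
#' other nodes of the node's component (isolated nodes get 0); unnormalized
#' betweenness with each unordered pair counted once. All paths unweighted.
#' The unnormalized scales match the keystone cutoffs in
#' [keystone_criteria()].
#'
#' @param network a `cooccurrence_network` or [igraph] graph.
#' @return data.frame with columns taxon_id, degree, closeness, betweenness.
#' @export
node_centrality <- function(network) {
  g <- if (inherits(network, "cooccurrence_network")) as_igraph(network) else network
  deg <- igraph::degree(g)
  clo <- suppressWarnings(igraph::closeness(g, mode = "all", normalized = FALSE))
  clo[!is.finite(clo)] <- 0 # isolated nodes
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  data.frame(taxon_id = igraph::V(g)$name, degree = as.numeric(deg),
             closeness = as.numeric(clo), betweenness = as.numeric(btw),
             stringsAsFactors = FALSE)
}

#' Whole-network topology summary
#'
#' Unweighted metrics: node and edge counts, mean degree (2E/N), diameter
#' and average shortest-path length over connected pairs only (NA for
#' edgeless graphs), mean unnormalized closeness and betweenness, Newman
#' modularity Q of a Louvain partition (resolution 1, seeded for
#' reproducibility), and the number of connected components.
#'
#' @param network a `cooccurrence_network`.
#' @param modularity_seed RNG seed for the Louvain restarts (recorded in
#'   the output).
#' @param modularity_restarts number of seeded Louvain restarts; the
#'   best-modularity partition is kept (Louvain is stochastic and a single
#'   run can stall in a local optimum on small graphs).
#' @return one-row data.frame (class `topology_summary`) with the community
#'   membership stored in attribute `"membership"`.
#' @export
topology_summary <- function(network, modularity_seed = 1L,
                             modularity_restarts = 20L) {
  g <- as_igraph(network)
  n_nodes <- igraph::vcount(g)
  if (n_nodes < 1L) abort("network has no nodes")
  n_edges <- igraph::ecount(g)
  cent <- node_centrality(g)
  comp <- igraph::components(g)
  if (n_edges > 0L) {
    diam <- igraph::diameter(g, directed = FALSE, unconnected = TRUE,
                             weights = NA)
    apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE,
                                 weights = NA)
    q <- -Inf
    membership <- NULL
    for (r in seq_len(modularity_restarts)) {
      cl <- with_seed(derive_seed(modularity_seed, paste0("louvain", r)),
                      igraph::cluster_louvain(g, resolution = 1))
      q_r <- igraph::modularity(g, igraph::membership(cl))
      if (q_r > q) {
        q <- q_r
        membership <- igraph::membership(cl)
      }
    }
  } else {
    diam <- NA_real_; apl <- NA_real_
    membership <- stats::setNames(seq_len(n_nodes), igraph::V(g)$name)
    q <- NA_real_
  }
  out <- data.frame(
    stratum = network$stratum, n_nodes = n_nodes, n_edges = n_edges,
    mean_degree = 2 * n_edges / n_nodes,
    diameter = as.numeric(diam), avg_path_length = apl,
    mean_closeness = mean(cent$closeness),
    mean_betweenness = mean(cent$betweenness),
    modularity = q, n_components = comp$no,
    modularity_seed = modularity_seed,
    stringsAsFactors = FALSE
  )
  attr(out, "membership") <- membership
  class(out) <- c("topology_summary", class(out))
  out
}

#' Keystone selection thresholds
#'
#' Joint centrality cutoffs defining keystone taxa: degree strictly above
#' `degree_min`, unnormalized closeness strictly above `closeness_min`, and
#' unnormalized betweenness strictly below `betweenness_max` - i.e. highly
#' connected nodes embedded inside well-knit neighbourhoods rather than
#' acting as bridges. Presets: `"fungi"` (5, 0.005, 40) and `"bacteria"`
#' (15, 0.03, 50), the conventional cutoffs for ITS and 16S soil networks
#' of a few hundred nodes.
#'
#' @param preset `"fungi"`, `"bacteria"`, or NULL to pass thresholds
#'   directly.
#' @param degree_min,closeness_min,betweenness_max numeric thresholds.
#' @return list of class `keystone_criteria`.
#' @export
keystone_criteria <- function(preset = NULL, degree_min = NULL,
                              closeness_min = NULL, betweenness_max = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("fungi", "bacteria"))
    vals <- switch(preset,
      fungi = list(degree_min = 5, closeness_min = 0.005, betweenness_max = 40),
      bacteria = list(degree_min = 15, closeness_min = 0.03, betweenness_max = 50))
    degree_min <- degree_min %||% vals$degree_min
    closeness_min <- closeness_min %||% vals$closeness_min
    betweenness_max <- betweenness_max %||% vals$betweenness_max
  }
  if (is.null(degree_min) || is.null(closeness_min) || is.null(betweenness_max)) {
    abort("keystone criteria need degree_min, closeness_min and betweenness_max (or a preset)")
  }
  if (degree_min < 0 || closeness_min < 0 || betweenness_max < 0) {
    abort("keystone thresholds must be nonnegative")
  }
  structure(list(degree_min = degree_min, closeness_min = closeness_min,
                 betweenness_max = betweenness_max, preset = preset),
            class = "keystone_criteria")
}

#' Identify keystone taxa in a network
#'
#' A taxon is a keystone iff degree > degree_min AND closeness >
#' closeness_min AND betweenness < betweenness_max, all inequalities strict.
#'
#' @param network a `cooccurrence_network`.
#' @param criteria a [keystone_criteria()] object.
#' @param centrality optional precomputed [node_centrality()] table for the
#'   same network.
#' @return character vector of keystone taxon_ids, lexicographically sorted.
#' @export
identify_keystones <- function(network, criteria, centrality = NULL) {
  if (!inherits(criteria, "keystone_criteria")) {
    criteria <- do.call(keystone_criteria, as.list(criteria))
  }
  cent <- centrality %||% node_centrality(network)
  hit <- cent$degree > criteria$degree_min &
    cent$closeness > criteria$closeness_min &
    cent$betweenness < criteria$betweenness_max
  sort(cent$taxon_id[hit])
}

#' One co-occurrence network per stratum
#'
#' Splits the samples by stratum label and builds each network independently
#' from that stratum's samples with identical settings, following the
#' construct-networks-per-land-use design. Each stratum needs at least
#' `min_samples` samples (correlation is meaningless below 4).
#'
#' @param x a [count_matrix] (typically rarefied).
#' @param metadata [sample_metadata()] covering every sample of `x`.
#' @param strata optional named character vector sample_id -> stratum;
#'   defaults to [stratum_labels()] of the metadata.
#' @param min_samples minimum samples per stratum (default 4).
#' @inheritParams build_network
#' @return named list of `cooccurrence_network`, one per stratum.
#' @export
per_stratum_networks <- function(x, metadata, strata = NULL, rho_min = 0.6,
                                 alpha = 0.05, positive_only = TRUE,
                                 min_samples = 4L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(strata)) {
    metadata <- sample_metadata(as.data.frame(metadata), counts = x)
    strata <- stratum_labels(metadata)
  }
  unmapped <- setdiff(sample_ids(x), names(strata))
  if (length(unmapped)) {
    abort("sample(s) without a stratum: %s", paste(unmapped, collapse = ", "))
  }
  strata <- strata[sample_ids(x)]
  sizes <- table(strata)
  if (any(sizes < min_samples)) {
    small <- names(sizes)[sizes < min_samples]
    abort("stratum '%s' has %d samples, fewer than %d",
          small[1L], sizes[small[1L]], min_samples)
  }
  nets <- lapply(sort(unique(strata)), function(s) {
    sub <- count_matrix(unclass(x)[, names(strata)[strata == s], drop = FALSE])
    corr <- spearman_matrix(sub)
    build_network(corr, rho_min = rho_min, alpha = alpha,
                  positive_only = positive_only, stratum = s, adjust = adjust)
  })
  names(nets) <- sort(unique(strata))
  nets
}
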