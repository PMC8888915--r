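# Independent brute-force graph oracles: all-pairs BFS, explicit
# shortest-path enumeration, exhaustive partition search for modularity.
# Deliberately naive and self-contained - no igraph calls anywhere.

bf_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ] > 0)) {
          if (d[s, u] > depth) {
            d[s, u] <- depth
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

bf_degree <- function(adj) rowSums(adj > 0)

# unnormalized closeness within the component; isolated nodes -> 0
bf_closeness <- function(adj) {
  d <- bf_dist(adj)
  vapply(seq_len(nrow(adj)), function(v) {
    reach <- d[v, is.finite(d[v, ])]
    s <- sum(reach)
    if (s == 0) 0 else 1 / s
  }, numeric(1))
}

# every shortest s-t path, as vectors of node indices
bf_paths <- function(adj, d, s, t) {
  if (s == t) return(list(s))
  preds <- which(adj[, t] > 0 & d[s, ] == d[s, t] - 1)
  out <- list()
  for (v in preds) {
    for (p in bf_paths(adj, d, s, v)) out <- c(out, list(c(p, t)))
  }
  out
}

# unnormalized betweenness, each unordered pair counted once
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_dist(adj)
  b <- numeric(n)
  if (n < 3) return(b)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(d[s, t]) || d[s, t] < 2) next
      paths <- bf_paths(adj, d, s, t)
      for (p in paths) {
        for (v in setdiff(p, c(s, t))) b[v] <- b[v] + 1 / length(paths)
      }
    }
  }
  b
}

bf_diameter <- function(adj) {
  d <- bf_dist(adj)
  finite <- d[is.finite(d) & d > 0]
  if (!length(finite)) NA_real_ else max(finite)
}

bf_avg_path_length <- function(adj) {
  d <- bf_dist(adj)
  ut <- d[upper.tri(d)]
  ut <- ut[is.finite(ut)]
  if (!length(ut)) NA_real_ else mean(ut)
}

# Newman modularity of a given membership vector
bf_modularity <- function(adj, membership) {
  deg <- rowSums(adj > 0)
  m <- sum(adj[upper.tri(adj)] > 0)
  if (m == 0) return(NA_real_)
  q <- 0
  for (c in unique(membership)) {
    nodes <- which(membership == c)
    e_c <- sum(adj[nodes, nodes, drop = FALSE] > 0) / 2
    d_c <- sum(deg[nodes])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# all set partitions of n elements via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(a, i, mx) {
    if (i > n) {
      out[[length(out) + 1]] <<- a
      return(invisible())
    }
    for (k in seq_len(mx + 1)) {
      a[i] <- k
      recurse(a, i + 1, max(mx, k))
    }
  }
  recurse(integer(n), 1L, 0L)
  out
}

bf_max_modularity <- function(adj) {
  best <- -Inf
  best_part <- NULL
  for (p in all_partitions(nrow(adj))) {
    q <- bf_modularity(adj, p)
    if (!is.na(q) && q > best) {
      best <- q
      best_part <- p
    }
  }
  list(q = best, membership = best_part)
}

# random connected simple graph: random spanning tree + extra random edges
random_connected_adj <- function(n, extra = NULL) {
  adj <- matrix(0L, n, n)
  if (n > 1) {
    for (v in 2:n) {
      u <- sample.int(v - 1, 1)
      adj[u, v] <- adj[v, u] <- 1L
    }
  }
  pairs <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
  if (is.null(extra)) extra <- sample(0:nrow(pairs), 1)
  extra <- min(extra, nrow(pairs))
  if (extra > 0) {
    pick <- pairs[sample.int(nrow(pairs), extra), , drop = FALSE]
    adj[pick] <- 1L
    adj[pick[, c(2, 1), drop = FALSE]] <- 1L
  }
  dimnames(adj) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  adj
}

# wrap an adjacency matrix as a cooccurrence_network (rho 1, p 0 per edge)
net_from_adj <- function(adj, stratum = "test") {
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(
    source = rownames(adj)[idx[, 1]], target = colnames(adj)[idx[, 2]],
    rho = rep(1, nrow(idx)), p = rep(0, nrow(idx)),
    stringsAsFactors = FALSE
  )
  structure(list(stratum = stratum, taxon_ids = rownames(adj), edges = edges,
                 rho_min = 0.6, alpha = 0.05, n_samples = NA_integer_),
            class = "cooccurrence_network")
}

# two triangles joined by a single bridge edge (6 nodes, 7 edges)
barbell_adj <- function() {
  adj <- matrix(0L, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  adj[edges] <- 1L
  adj[edges[, c(2, 1)]] <- 1L
  adj
}

# craft a correlation_matrix object directly
corr_from <- function(rho, p, n = 30L) {
  structure(list(taxon_ids = rownames(rho), rho = rho, p = p, n = n,
                 excluded = character(0)),
            class = "correlation_matrix")
}

# bare integer matrix: strips count_matrix class and bookkeeping attributes
bare <- function(x) {
  x <- unclass(x)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

sym_mat <- function(ids, fill_rho, fill_p) {
  k <- length(ids)
  rho <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  p <- rho
  diag(rho) <- 1
  diag(p) <- 0
  list(rho = rho, p = p)
}
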