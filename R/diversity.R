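#' Hill-number diversity of one sample
#'
#' Hill diversity of order q: q = 0 is OTU richness (the number of taxa with
#' at least one read); q = 1 is the exponential of Shannon entropy,
#' exp(-sum p_i log p_i), the effective number of equally common taxa.
#' Natural logarithms are used inside the entropy; the exponential undoes
#' the base so the result is base-free.
#'
#' @param counts nonnegative integer vector of one sample's reads.
#' @param order 0 or 1.
#' @return a single number; for order 1 it lies in \[1, richness\].
#' @examples
#' hill_diversity(c(10, 10, 10, 10), order = 1) # perfectly even: 4
#' hill_diversity(c(70, 10, 10, 10, 0), order = 0) # richness: 4
#' @export
hill_diversity <- function(counts, order = c(0, 1)) {
  order <- order[1L]
  if (!order %in% c(0, 1)) abort("order must be 0 or 1")
  if (any(counts < 0)) abort("negative count")
  total <- sum(counts)
  if (total == 0) abort("all-zero count vector: diversity undefined")
  if (order == 0) return(sum(counts > 0))
  p <- counts[counts > 0] / total
  exp(-sum(p * log(p)))
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting the taxa
#' observed in a sample. By default the subtree includes the path to the
#' root (root-inclusive convention, the most common one); with
#' `include_root = FALSE` the branches above the most recent common ancestor
#' of the observed leaves are excluded. Presence-only: abundances beyond
#' presence/absence are ignored.
#'
#' @param counts nonnegative numeric vector of reads, parallel to
#'   `taxon_ids`.
#' @param taxon_ids taxon labels matching tree tip labels.
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param strict if TRUE (default), observed taxa missing from the tree are
#'   an error; if FALSE the observed set is intersected with the tree's
#'   leaves (with a warning).
#' @param include_root include the root path (default TRUE).
#' @return Faith's PD in branch-length units.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' faith_pd(c(1, 0, 1), c("A", "B", "C"), tr) # 4: A + stem + C
#' @export
faith_pd <- function(counts, taxon_ids, tree, strict = TRUE,
                     include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"), length(counts) == length(taxon_ids))
  observed <- as.character(taxon_ids[counts > 0])
  if (!length(observed)) abort("no observed taxa: PD undefined")
  missing <- setdiff(observed, tree$tip.label)
  if (length(missing)) {
    if (strict) {
      abort("observed taxa missing from tree: %s", paste(missing, collapse = ", "))
    }
    warn("dropping %d observed taxa absent from tree", length(missing))
    observed <- setdiff(observed, missing)
    if (!length(observed)) abort("no observed taxa left after intersecting with tree")
  }
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  # union of root-paths of the observed leaves
  used <- logical(nrow(tree$edge))
  for (tip in match(observed, tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- edge_of[node]
      if (used[e]) break # remainder of this path already collected
      used[e] <- TRUE
      node <- parent_of[node]
    }
  }
  pd <- sum(tree$edge.length[used])
  if (!include_root) {
    # strip the chain from the root down to the MRCA of the observed set
    tips <- match(observed, tree$tip.label)
    mrca <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    node <- mrca
    while (node != root) {
      e <- edge_of[node]
      pd <- pd - tree$edge.length[e]
      node <- parent_of[node]
    }
  }
  pd
}

#' Per-sample diversity table
#'
#' Computes OTU richness (Hill order 0), Hill order 1, and (when a tree is
#' supplied) Faith's PD for every sample of a count matrix.
#'
#' @param x a [count_matrix].
#' @param tree optional rooted [ape::phylo] tree covering the observed taxa.
#' @inheritParams faith_pd
#' @return data.frame with columns sample_id, richness, hill1 and, when a
#'   tree is given, faith_pd.
#' @export
diversity_table <- function(x, tree = NULL, strict = TRUE,
                            include_root = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  m <- unclass(x)
  res <- data.frame(
    sample_id = colnames(m),
    richness = apply(m, 2L, function(v) hill_diversity(v, 0)),
    hill1 = apply(m, 2L, function(v) hill_diversity(v, 1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(tree)) {
    res$faith_pd <- apply(m, 2L, function(v) {
      faith_pd(v, rownames(m), tree, strict = strict,
               include_root = include_root)
    })
  }
  rownames(res) <- NULL
  res
}
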