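#' Rarefy a count matrix to even depth
#'
#' Randomly subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to a common depth, the standard correction for
#' uneven library sizes before diversity or network analysis. Conventional
#' depths for soil amplicon data are 10,000 reads for fungal (ITS) and
#' 20,000 for bacterial (16S) libraries; these are exposed as
#' `default_rarefaction_depth()`.
#'
#' Each sample gets its own RNG stream derived deterministically from
#' `(seed, sample_id)`, so results never depend on sample order and a fixed
#' seed gives bit-identical output.
#'
#' @param x a [count_matrix].
#' @param depth target reads per sample (positive integer).
#' @param seed integer seed governing all subsampling.
#' @param drop_shallow if TRUE, samples with fewer than `depth` reads are
#'   dropped (with a warning); if FALSE (default) they are an error.
#' @param drop_empty_taxa if TRUE, taxa left with zero reads in every sample
#'   are removed; otherwise retained and listed in the `"empty_taxa"`
#'   attribute.
#' @return a [count_matrix] in which every retained sample sums exactly to
#'   `depth` and every count is at most its original value.
#' @examples
#' cm <- count_matrix(matrix(c(50, 30, 20, 10, 5, 0), 3, 2,
#'   dimnames = list(paste0("t", 1:3), c("a", "b"))))
#' colSums(rarefy_counts(cm, depth = 10, seed = 1))
#' @export
rarefy_counts <- function(x, depth, seed, drop_shallow = FALSE,
                          drop_empty_taxa = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(depth) != 1L || !is_wholenumber(depth) || depth <= 0) {
    abort("depth must be a single positive integer (got %s)", format(depth))
  }
  depth <- as.integer(round(depth))
  totals <- sample_depths(x)
  shallow <- names(totals)[totals < depth]
  if (length(shallow)) {
    if (!drop_shallow) {
      abort("sample '%s' has %d reads, fewer than depth %d (set drop_shallow to discard)",
            shallow[1L], totals[shallow[1L]], depth)
    }
    warn("dropping %d sample(s) below depth %d: %s",
         length(shallow), depth, paste(shallow, collapse = ", "))
  }
  keep <- setdiff(sample_ids(x), shallow)
  if (!length(keep)) abort("no sample reaches depth %d", depth)
  m <- unclass(x)[, keep, drop = FALSE]
  out <- m
  for (s in keep) {
    out[, s] <- rarefy_one(m[, s], depth, derive_seed(seed, s))
  }
  empty <- rownames(out)[rowSums(out) == 0L]
  if (drop_empty_taxa && length(empty)) {
    out <- out[setdiff(rownames(out), empty), , drop = FALSE]
  }
  res <- count_matrix(out)
  attr(res, "empty_taxa") <- if (drop_empty_taxa) character(0) else empty
  attr(res, "rarefaction") <- list(depth = depth, seed = seed,
                                   dropped_samples = shallow)
  res
}

# hypergeometric draw of `depth` reads from one sample's count vector
rarefy_one <- function(counts, depth, seed) {
  total <- sum(counts)
  if (total == depth) return(counts)
  occupied <- which(counts > 0L)
  pool <- rep.int(occupied, counts[occupied])
  with_seed(seed, {
    drawn <- pool[sample.int(total, depth)]
    tabulate(drawn, nbins = length(counts))
  })
}

#' @rdname rarefy_counts
#' @param kingdom `"fungi"` or `"bacteria"`.
#' @export
default_rarefaction_depth <- function(kingdom = c("fungi", "bacteria")) {
  switch(match.arg(kingdom), fungi = 10000L, bacteria = 20000L)
}

#' Closed-form expected richness under rarefaction
#'
#' Hypergeometric expectation of the number of taxa retained when `depth`
#' reads are drawn without replacement from a sample:
#' E\[S\] = sum_i (1 - choose(total - n_i, depth) / choose(total, depth)).
#' Used as the analytic reference for calibration checks.
#'
#' @param counts nonnegative integer vector of one sample's reads.
#' @param depth subsample size.
#' @return expected number of taxa with at least one read after rarefaction.
#' @export
expected_rarefied_richness <- function(counts, depth) {
  total <- sum(counts)
  stopifnot(depth <= total)
  n <- counts[counts > 0]
  # log-scale ratio of binomial coefficients for numerical safety
  pr_absent <- exp(lchoose(total - n, depth) - lchoose(total, depth))
  pr_absent[total - n < depth] <- 0
  sum(1 - pr_absent)
}
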