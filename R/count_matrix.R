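#' OTU count matrix (taxa x samples)
#'
#' The central exchange object of the package: a nonnegative integer matrix
#' of read counts with taxa as rows and samples as columns. Row and column
#' names are the taxon and sample identifiers and must be unique.
#'
#' @param counts numeric matrix (or object coercible to one) of nonnegative
#'   integer read counts, taxa in rows, samples in columns.
#' @param taxon_ids,sample_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return a `count_matrix`: an integer matrix with class
#'   `c("count_matrix", "matrix", "array")`.
#' @examples
#' cm <- count_matrix(matrix(c(3, 1, 0, 2), 2, 2,
#'   dimnames = list(c("OTU1", "OTU2"), c("S1", "S2"))))
#' sample_depths(cm)
#' @export
count_matrix <- function(counts, taxon_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids) || is.null(sample_ids)) {
    abort("count_matrix needs taxon and sample identifiers (dimnames)")
  }
  dimnames(counts) <- list(as.character(taxon_ids), as.character(sample_ids))
  validate_count_matrix(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_matrix", "matrix", "array")
  counts
}

validate_count_matrix <- function(counts) {
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    abort("count matrix must have at least 1 taxon and 1 sample")
  }
  if (anyDuplicated(rownames(counts))) {
    abort("duplicate taxon identifier: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    abort("duplicate sample identifier: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                collapse = ", "))
  }
  bad <- which(!is_wholenumber(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort("non-integer or negative count at (taxon '%s', sample '%s'): %s",
          rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
          format(counts[bad[1L, , drop = FALSE]]))
  }
  invisible(counts)
}

#' @rdname count_matrix
#' @param x a `count_matrix`.
#' @export
taxon_ids <- function(x) rownames(x)

#' @rdname count_matrix
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname count_matrix
#' @return `sample_depths()`: named integer vector of per-sample read totals.
#' @export
sample_depths <- function(x) colSums(unclass(x))

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d taxa x %d samples, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  cat(sprintf("  per-sample depth: %s .. %s\n",
              format(min(sample_depths(x))), format(max(sample_depths(x)))))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' Checks the contract for per-sample metadata: unique `sample_id`;
#' `land_use` one of IPM / organic / grassland; `location` one of crop_row /
#' drive_row / none, with `none` if and only if the sample is grassland.
#' Nesting columns (`site_id`, `plot_id`, `subplot_id`) and soil covariates
#' are carried through untouched.
#'
#' @param metadata data.frame with at least columns `sample_id`, `land_use`,
#'   `location`.
#' @param counts optional `count_matrix`; when given, every sample of the
#'   matrix must have a metadata row.
#' @return the validated data.frame, invisibly classed `sample_metadata`.
#' @export
sample_metadata <- function(metadata, counts = NULL) {
  need <- c("sample_id", "land_use", "location")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) abort("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) {
    abort("duplicate sample_id in metadata: %s",
          paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
                collapse = ", "))
  }
  if (!all(metadata$land_use %in% c("IPM", "organic", "grassland"))) {
    abort("land_use must be one of IPM, organic, grassland")
  }
  if (!all(metadata$location %in% c("crop_row", "drive_row", "none"))) {
    abort("location must be one of crop_row, drive_row, none")
  }
  bad <- xor(metadata$location == "none", metadata$land_use == "grassland")
  if (any(bad)) {
    abort("location 'none' must coincide exactly with land_use 'grassland' (sample %s)",
          metadata$sample_id[which(bad)[1L]])
  }
  if (!is.null(counts)) {
    absent <- setdiff(sample_ids(counts), metadata$sample_id)
    if (length(absent)) {
      abort("samples missing from metadata: %s", paste(absent, collapse = ", "))
    }
  }
  class(metadata) <- unique(c("sample_metadata", class(metadata)))
  metadata
}

#' Stratum label of each sample
#'
#' Samples are grouped into land-use strata: grassland samples form the
#' `grassland` stratum; orchard samples are labelled
#' `<land_use>_<location>` (e.g. `IPM_crop_row`), giving the five strata of
#' a management x location design plus the semi-natural reference.
#'
#' @param metadata validated sample metadata.
#' @return character vector of stratum labels, named by sample_id.
#' @export
stratum_labels <- function(metadata) {
  lab <- ifelse(metadata$land_use == "grassland", "grassland",
                paste(metadata$land_use, metadata$location, sep = "_"))
  names(lab) <- metadata$sample_id
  lab
}
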