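#' Aggregate read counts by functional guild
#'
#' Sums each sample's reads over the taxa annotated with each requested
#' guild (single-label model: a taxon contributes to exactly one guild).
#' Taxa annotated `unassigned`, and taxa absent from the guild table,
#' contribute to no guild; per sample, guild totals plus the unassigned
#' remainder always equal the sample total.
#'
#' @param x a [count_matrix] (typically rarefied).
#' @param guilds a [guild_table()] data.frame.
#' @param guild_names guilds to report; default: every annotated guild
#'   except `unassigned`.
#' @param include_unassigned add an `unassigned` column holding the
#'   remainder (default FALSE).
#' @return data.frame, one row per sample: sample_id then one integer
#'   column per guild.
#' @examples
#' cm <- count_matrix(matrix(c(5, 2, 7), 3, 1,
#'   dimnames = list(c("t1", "t2", "t3"), "s1")))
#' gt <- data.frame(taxon_id = c("t1", "t2", "t3"), kingdom = "fungi",
#'   guild = c("AMF", "AMF", "saprotroph"))
#' guild_read_counts(cm, gt)
#' @export
guild_read_counts <- function(x, guilds, guild_names = NULL,
                              include_unassigned = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  guilds <- guild_table(as.data.frame(guilds))
  known <- setdiff(unique(guilds$guild), "unassigned")
  if (is.null(guild_names)) guild_names <- sort(known)
  unknown <- setdiff(guild_names, known)
  if (length(unknown)) {
    abort("unknown guild(s): %s; known guilds: %s",
          paste(unknown, collapse = ", "),
          paste(sort(known), collapse = ", "))
  }
  m <- unclass(x)
  assignment <- guilds$guild[match(rownames(m), guilds$taxon_id)]
  assignment[is.na(assignment)] <- "unassigned"
  if (all(assignment == "unassigned")) {
    warn("all taxa unassigned: guild counts are all zero")
  }
  out <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  for (g in guild_names) {
    sel <- assignment == g
    out[[g]] <- as.integer(colSums(m[sel, , drop = FALSE]))
  }
  if (include_unassigned) {
    counted <- assignment %in% guild_names
    out[["unassigned"]] <- as.integer(colSums(m) -
                                        colSums(m[counted, , drop = FALSE]))
  }
  out
}

#' Most abundant guilds
#'
#' Ranks annotated guilds (excluding `unassigned`) by their total read
#' count across all samples and returns the top `k`; ties are broken
#' lexicographically. Used e.g. to pick the dominant bacterial metabolic
#' groups for downstream modelling.
#'
#' @inheritParams guild_read_counts
#' @param k number of guilds to return.
#' @return character vector of up to `k` guild names.
#' @export
dominant_guilds <- function(x, guilds, k) {
  if (k < 1L) abort("k must be at least 1")
  counts <- guild_read_counts(x, guilds)
  totals <- vapply(counts[-1L], sum, numeric(1))
  if (k > length(totals)) {
    warn("only %d assigned guild(s) available (k = %d): returning all",
         length(totals), k)
    k <- length(totals)
  }
  ord <- order(-totals, names(totals))
  names(totals)[ord][seq_len(k)]
}
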