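# IO: tab-separated tables, newick trees, GraphML / edge-list networks.
# All tables are TSV, UTF-8, no quoting, "." decimal separator.

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

write_tsv_strict <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE,
                     fileEncoding = "UTF-8")
}

#' Read an OTU count table
#'
#' Tab-separated text, first column = row identifiers, header = column
#' identifiers. The table may be stored either as taxa-in-rows (the classic
#' OTU table convention) or samples-in-rows; the declared orientation is
#' normalized so the result is always taxa x samples. Orientation is an
#' explicit flag, never auto-detected, to avoid silent transposition.
#'
#' @param path file path.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @return a [count_matrix].
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) abort("count table '%s' has no data columns", path)
  row_ids <- as.character(df[[1L]])
  cells <- df[-1L]
  for (j in seq_along(cells)) {
    v <- cells[[j]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v) | !is_wholenumber(v) | v < 0)
    if (length(bad)) {
      abort("non-integer or negative cell at (row '%s', column '%s'): '%s'",
            row_ids[bad[1L]], names(cells)[j], as.character(cells[[j]][bad[1L]]))
    }
    cells[[j]] <- v
  }
  m <- as.matrix(cells)
  rownames(m) <- row_ids
  if (orientation == "samples_rows") m <- t(m)
  count_matrix(m)
}

#' Write an OTU count table
#'
#' @param x a [count_matrix].
#' @param path file path.
#' @param orientation stored orientation, as in [read_count_table()].
#' @param id_column header for the identifier column.
#' @export
write_count_table <- function(x, path, orientation = c("taxa_rows", "samples_rows"),
                              id_column = "taxon_id") {
  orientation <- match.arg(orientation)
  m <- unclass(x)
  if (orientation == "samples_rows") {
    m <- t(m)
    if (id_column == "taxon_id") id_column <- "sample_id"
  }
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write_tsv_strict(df, path)
  invisible(path)
}

#' Read / write sample metadata
#'
#' TSV with columns `sample_id`, `land_use`, `location`, nesting columns and
#' optional soil covariates; validated by [sample_metadata()].
#' @param path file path.
#' @return validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(read_tsv_strict(path))
}

#' @rdname read_sample_metadata
#' @param metadata metadata table.
#' @export
write_sample_metadata <- function(metadata, path) {
  write_tsv_strict(as.data.frame(metadata), path)
  invisible(path)
}

#' Read / write a guild annotation table
#'
#' One row per taxon with columns `taxon_id`, `kingdom` (fungi / bacteria)
#' and a single `guild` label; unannotated taxa carry `unassigned`.
#' Multi-guild annotations (rows sharing a taxon_id, or labels containing
#' `|` or `,`) are rejected: collapse them to one label per taxon upstream.
#'
#' @param path file path.
#' @return data.frame with columns taxon_id, kingdom, guild.
#' @export
read_guild_table <- function(path) {
  df <- read_tsv_strict(path)
  guild_table(df)
}

#' @rdname read_guild_table
#' @param guilds guild table.
#' @export
write_guild_table <- function(guilds, path) {
  write_tsv_strict(guild_table(guilds), path)
  invisible(path)
}

#' @rdname read_guild_table
#' @param df data.frame to validate.
#' @export
guild_table <- function(df) {
  need <- c("taxon_id", "kingdom", "guild")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("guild table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$taxon_id)) {
    abort(paste0("taxon '%s' has multiple guild rows; this package uses a ",
                 "single-label guild model - collapse multi-guild annotations ",
                 "to one label per taxon before import"),
          df$taxon_id[duplicated(df$taxon_id)][1L])
  }
  multi <- grepl("[|,]", df$guild)
  if (any(multi)) {
    abort(paste0("guild label '%s' (taxon '%s') looks multi-valued; collapse ",
                 "to a single label per taxon before import"),
          df$guild[multi][1L], df$taxon_id[multi][1L])
  }
  if (!all(df$kingdom %in% c("fungi", "bacteria"))) {
    abort("kingdom must be 'fungi' or 'bacteria'")
  }
  df[c("taxon_id", "kingdom", "guild")]
}

#' Read a newick tree
#'
#' Single rooted tree with branch lengths. Missing branch lengths default to
#' 0 with a warning; unbalanced parentheses and duplicate leaf labels are
#' errors.
#'
#' @param path file path (or a literal newick string ending in ";").
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  txt <- if (grepl(";\\s*$", path) && !file.exists(path)) path else
    paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close) {
    abort("unbalanced parentheses in newick ('(' x%d vs ')' x%d)", n_open, n_close)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) abort("could not parse newick tree")
  if (anyDuplicated(tree$tip.label)) {
    abort("duplicate leaf label in tree: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  n_edge <- nrow(tree$edge)
  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, n_edge)
  } else if (anyNA(tree$edge.length)) {
    warn("%d missing branch length(s) defaulted to 0", sum(is.na(tree$edge.length)))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) abort("negative branch length in tree")
  tree
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a co-occurrence network
#'
#' GraphML carries node attributes (taxon_id, degree, closeness, betweenness,
#' keystone flag) and edge attributes (rho, p); the edge-list TSV has columns
#' source, target, rho, p. Empty networks yield a header-only edge list or a
#' GraphML file of isolated nodes.
#'
#' @param network a `cooccurrence_network` (see [build_network()]).
#' @param path output file path.
#' @param format `"graphml"` or `"edge_list_tsv"`.
#' @param criteria optional [keystone_criteria()]; when supplied the GraphML
#'   keystone flag is computed with [identify_keystones()], otherwise all
#'   FALSE.
#' @export
write_network <- function(network, path,
                          format = c("graphml", "edge_list_tsv"),
                          criteria = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(network, "cooccurrence_network"))
  if (format == "edge_list_tsv") {
    write_tsv_strict(network$edges, path)
    return(invisible(path))
  }
  g <- as_igraph(network)
  cent <- node_centrality(network)
  idx <- match(igraph::V(g)$name, cent$taxon_id)
  igraph::V(g)$taxon_id <- igraph::V(g)$name
  igraph::V(g)$degree <- cent$degree[idx]
  igraph::V(g)$closeness <- cent$closeness[idx]
  igraph::V(g)$betweenness <- cent$betweenness[idx]
  keys <- if (is.null(criteria)) character(0) else
    identify_keystones(network, criteria = criteria)
  igraph::V(g)$keystone <- igraph::V(g)$name %in% keys
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network
#' @return `read_network_graphml()`: the network as an [igraph] graph.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
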