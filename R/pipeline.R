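#' Run the full community-structure pipeline
#'
#' One-command orchestration: read inputs, restrict samples to the chosen
#' stratification, rarefy to even depth, compute per-sample diversity,
#' build per-stratum co-occurrence networks with topology summaries and
#' keystone taxa, run the indicator analysis with its bipartite association
#' network, aggregate guild read counts, and write a machine-readable run
#' manifest. Rerunning with the same config and seed reproduces
#' byte-identical numeric outputs.
#'
#' Stratification presets:
#' - `"management"`: orchard samples only, 4 strata (IPM/organic x
#'   crop/drive row).
#' - `"land_use"`: crop rows omitted, 3 strata (IPM drive row, organic
#'   drive row, grassland) - the conservative comparison against the
#'   semi-natural benchmark.
#' - `"all"`: all 5 strata.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Keys: `counts`, `metadata` (paths, required), `tree`, `guilds`
#'   (optional paths), `depth` (rarefaction depth), `seed`,
#'   `stratification`, `rho_min`, `alpha`, `keystone_preset`, `n_perm`,
#'   `guild_select` (optional vector), `drop_shallow`, `out_dir`.
#' @param out_dir output directory; overrides the config key.
#' @return invisibly, a list with the main result objects and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(depth = 10000L, seed = 1L, stratification = "all",
                   rho_min = 0.6, alpha = 0.05, keystone_preset = "fungi",
                   n_perm = 999L, drop_shallow = FALSE)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) abort("no output directory given")
  if (!cfg$stratification %in% c("management", "land_use", "all")) {
    abort("stratification must be one of management, land_use, all")
  }

  # fail before any computation if an input is missing
  for (k in c("counts", "metadata")) {
    if (is.null(cfg[[k]])) abort("config key '%s' is required", k)
  }
  inputs <- c(counts = cfg$counts, metadata = cfg$metadata,
              tree = cfg$tree, guilds = cfg$guilds)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    abort("input file(s) not found: %s", paste(missing, collapse = ", "))
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    status = "incomplete",
    started = format(Sys.time(), tz = "UTC"),
    parameters = cfg[setdiff(names(cfg), c("counts", "metadata", "tree",
                                           "guilds"))],
    package_version = as.character(utils::packageVersion("soilcomm")),
    r_version = R.version.string,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  log_stage <- function(fmt, ...) message(sprintf(paste0("[pipeline] ", fmt), ...))

  counts <- read_count_table(cfg$counts)
  metadata <- read_sample_metadata(cfg$metadata)
  metadata <- sample_metadata(metadata, counts = counts)
  tree <- if (!is.null(cfg$tree)) read_newick(cfg$tree) else NULL
  guilds <- if (!is.null(cfg$guilds)) read_guild_table(cfg$guilds) else NULL
  log_stage("loaded %d taxa x %d samples", nrow(counts), ncol(counts))

  keep <- switch(cfg$stratification,
    management = metadata$sample_id[metadata$land_use != "grassland"],
    land_use = metadata$sample_id[metadata$location != "crop_row"],
    all = metadata$sample_id
  )
  keep <- intersect(sample_ids(counts), keep)
  if (!length(keep)) abort("no samples left after stratification '%s'",
                           cfg$stratification)
  counts <- count_matrix(unclass(counts)[, keep, drop = FALSE])
  metadata <- metadata[match(keep, metadata$sample_id), , drop = FALSE]
  strata <- stratum_labels(metadata)
  log_stage("stratification '%s': %d samples in %d strata (%s)",
            cfg$stratification, length(keep), length(unique(strata)),
            paste(sort(unique(strata)), collapse = ", "))

  rarefied <- rarefy_counts(counts, depth = cfg$depth, seed = cfg$seed,
                            drop_shallow = isTRUE(cfg$drop_shallow),
                            drop_empty_taxa = TRUE)
  strata <- strata[sample_ids(rarefied)]
  metadata <- metadata[match(sample_ids(rarefied), metadata$sample_id), ,
                       drop = FALSE]
  write_count_table(rarefied, file.path(out_dir, "rarefied_counts.tsv"))
  log_stage("rarefied to depth %d: %d taxa x %d samples retained",
            cfg$depth, nrow(rarefied), ncol(rarefied))

  div <- diversity_table(rarefied, tree = tree, strict = FALSE)
  write_tsv_strict(div, file.path(out_dir, "diversity.tsv"))
  log_stage("diversity computed for %d samples", nrow(div))

  nets <- suppressWarnings(
    per_stratum_networks(rarefied, metadata, rho_min = cfg$rho_min,
                         alpha = cfg$alpha)
  )
  criteria <- keystone_criteria(cfg$keystone_preset)
  topo <- do.call(rbind, lapply(nets, topology_summary))
  rownames(topo) <- NULL
  keystones <- do.call(rbind, lapply(nets, function(net) {
    ks <- identify_keystones(net, criteria)
    if (!length(ks)) return(NULL)
    data.frame(stratum = net$stratum, taxon_id = ks, stringsAsFactors = FALSE)
  }))
  if (is.null(keystones)) {
    keystones <- data.frame(stratum = character(0), taxon_id = character(0))
  }
  for (net in nets) {
    stem <- file.path(out_dir, "networks", net$stratum)
    write_network(net, paste0(stem, ".graphml"), "graphml",
                  criteria = criteria)
    write_network(net, paste0(stem, "_edges.tsv"), "edge_list_tsv")
  }
  write_tsv_strict(as.data.frame(topo), file.path(out_dir, "topology.tsv"))
  write_tsv_strict(keystones, file.path(out_dir, "keystones.tsv"))
  log_stage("networks: %s edges; %d keystone taxa total",
            paste(sprintf("%s=%d", topo$stratum, topo$n_edges),
                  collapse = ", "), nrow(keystones))

  ind <- suppressWarnings(
    indicator_analysis(rarefied, strata, n_perm = cfg$n_perm,
                       seed = cfg$seed)
  )
  write_tsv_strict(as.data.frame(ind), file.path(out_dir, "indicator_table.tsv"))
  assoc <- association_network(ind, alpha = cfg$alpha)
  igraph::write_graph(assoc$graph,
                      file.path(out_dir, "association_network.graphml"),
                      format = "graphml")
  log_stage("indicator analysis: %d/%d taxa significant at p < %g",
            assoc$n_significant, nrow(ind), cfg$alpha)

  guild_counts <- NULL
  if (!is.null(guilds)) {
    guild_counts <- suppressWarnings(
      guild_read_counts(rarefied, guilds,
                        guild_names = cfg$guild_select %||% NULL,
                        include_unassigned = TRUE)
    )
    write_tsv_strict(guild_counts, file.path(out_dir, "guild_counts.tsv"))
    log_stage("guild counts written for %d guilds", ncol(guild_counts) - 2L)
  }

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, manifest_path)
  manifest$status <- "complete"
  manifest$finished <- format(Sys.time(), tz = "UTC")
  manifest$outputs <- lapply(outputs, function(p) {
    list(path = sub(paste0("^", out_dir, "/?"), "", p),
         md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(rarefied = rarefied, diversity = div, networks = nets,
                 topology = topo, keystones = keystones, indicators = ind,
                 association = assoc, guild_counts = guild_counts,
                 manifest = manifest, out_dir = out_dir))
}
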