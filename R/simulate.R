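# Planted-structure community simulator: latent-factor copula on
# log-abundances, Dirichlet-multinomial counts, random tree, guild labels.

#' Simulation configuration
#'
#' Describes a synthetic amplicon survey with planted, recoverable
#' structure. Samples are organized in land-use strata with nested
#' site/plot identifiers. Taxon log-abundances are
#' base + stratum effects + correlated latent structure + unit Gaussian
#' noise; correlation is planted through per-module latent factors
#' (loading lambda gives within-module latent correlation lambda^2), active
#' only in the module's stratum. Hub groups are modules written as a hub
#' taxon plus `partners` partner taxa, so the hub's planted degree equals
#' `partners`. Indicator taxa get a fixed log-fold-change in every sample
#' of their stratum combination. Counts are Dirichlet-multinomial at a
#' log-normally distributed depth (truncated at 1,000 reads).
#'
#' @param n_taxa total number of taxa.
#' @param strata data.frame with columns land_use, location, n_samples.
#' @param depth_mean,depth_sd mean reads per sample and log-scale sd of the
#'   log-normal depth distribution.
#' @param modules list of lists with `taxon_count`, `loading` in (0, 1\],
#'   `stratum`.
#' @param hubs list of lists with `partners`, `loading`, `stratum`.
#' @param indicators list of lists with `combo` (character vector of
#'   strata) and `lfc` (log-fold-change).
#' @param guild_fractions named numeric vector of guild proportions summing
#'   to at most 1 (remainder unassigned).
#' @param base_abundance c(mean, sd) of taxon base log-abundance.
#' @param planted_base c(mean, sd) of base log-abundance for module and hub
#'   taxa; the default centres planted structure on the moderately abundant
#'   community fraction where rank correlations are estimable.
#' @param overdispersion Dirichlet-multinomial concentration (larger =
#'   closer to multinomial).
#' @param kingdom `"fungi"` or `"bacteria"` (guild table annotation).
#' @param seed integer seed making the whole simulation deterministic.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa, strata, depth_mean = 15000,
                              depth_sd = 0.2, modules = list(),
                              hubs = list(), indicators = list(),
                              guild_fractions = c(saprotroph = 0.3,
                                                  AMF = 0.1,
                                                  plant_pathogen = 0.1),
                              base_abundance = c(0, 1),
                              planted_base = c(1, 0.5),
                              overdispersion = 10000,
                              kingdom = "fungi", seed = 1L) {
  strata <- as.data.frame(strata)
  stopifnot(all(c("land_use", "location", "n_samples") %in% names(strata)))
  cfg <- structure(list(
    n_taxa = as.integer(n_taxa), strata = strata, depth_mean = depth_mean,
    depth_sd = depth_sd, modules = modules, hubs = hubs,
    indicators = indicators, guild_fractions = guild_fractions,
    base_abundance = base_abundance, planted_base = planted_base,
    overdispersion = overdispersion,
    kingdom = kingdom, seed = as.integer(seed)
  ), class = "simulation_config")
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  groups <- c(cfg$modules,
              lapply(cfg$hubs, function(h) {
                list(taxon_count = h$partners + 1L, loading = h$loading,
                     stratum = h$stratum)
              }))
  planted <- sum(vapply(groups, function(g) g$taxon_count, numeric(1))) +
    length(cfg$indicators)
  if (planted > cfg$n_taxa) {
    abort("planted structure needs %d taxa but n_taxa = %d", planted, cfg$n_taxa)
  }
  loadings <- vapply(groups, function(g) g$loading, numeric(1))
  if (length(loadings) && any(loadings <= 0 | loadings > 1)) {
    abort("loadings must lie in (0, 1]")
  }
  if (sum(cfg$guild_fractions) > 1 + 1e-9) {
    abort("guild fractions must sum to at most 1")
  }
  strat_names <- simulated_stratum_names(cfg$strata)
  for (ind in cfg$indicators) {
    bad <- setdiff(ind$combo, strat_names)
    if (length(bad)) abort("indicator combo names unknown stratum: %s",
                           paste(bad, collapse = ", "))
  }
  for (g in groups) {
    if (!g$stratum %in% strat_names) abort("unknown module stratum '%s'", g$stratum)
  }
  cfg
}

simulated_stratum_names <- function(strata) {
  ifelse(strata$land_use == "grassland", "grassland",
         paste(strata$land_use, strata$location, sep = "_"))
}

#' Simulate a community survey with planted structure
#'
#' Generates a count matrix, nested sample metadata, a random bifurcating
#' phylogeny with exponential branch lengths, a guild table, and the ground
#' truth needed to score recovery (module membership, hub taxa, indicator
#' combos, per-stratum mean relative abundances). Fully deterministic given
#' the config seed.
#'
#' @param config a [simulation_config()].
#' @return list of class `community_simulation` with elements `counts`
#'   ([count_matrix]), `metadata`, `tree`, `guilds`, `truth`, `config`.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  with_seed(config$seed, simulate_community_impl(config))
}

simulate_community_impl <- function(cfg) {
  n_taxa <- cfg$n_taxa
  taxa <- sprintf("OTU%04d", seq_len(n_taxa))

  # --- metadata with nested site/plot structure (3 plots per site) ---
  strat_names <- simulated_stratum_names(cfg$strata)
  meta <- do.call(rbind, lapply(seq_len(nrow(cfg$strata)), function(i) {
    n <- cfg$strata$n_samples[i]
    site <- ceiling(seq_len(n) / 3)
    data.frame(
      land_use = cfg$strata$land_use[i], location = cfg$strata$location[i],
      site_id = sprintf("%s_site%02d", strat_names[i], site),
      plot_id = sprintf("%s_site%02d_plot%d", strat_names[i], site,
                        ((seq_len(n) - 1L) %% 3L) + 1L),
      stringsAsFactors = FALSE
    )
  }))
  meta$sample_id <- sprintf("S%04d", seq_len(nrow(meta)))
  meta$subplot_id <- paste(meta$plot_id, meta$location, sep = "_")
  meta <- meta[c("sample_id", "land_use", "location", "site_id", "plot_id",
                 "subplot_id")]
  meta <- sample_metadata(meta)
  stratum <- unname(stratum_labels(meta))
  n_samples <- nrow(meta)

  # --- role assignment: modules, hub groups, indicators, background ---
  groups <- c(
    lapply(cfg$modules, function(m) {
      list(size = m$taxon_count, loading = m$loading, stratum = m$stratum,
           type = "module")
    }),
    lapply(cfg$hubs, function(h) {
      list(size = h$partners + 1L, loading = h$loading, stratum = h$stratum,
           type = "hub_group")
    })
  )
  cursor <- 0L
  for (k in seq_along(groups)) {
    groups[[k]]$taxa <- taxa[cursor + seq_len(groups[[k]]$size)]
    cursor <- cursor + groups[[k]]$size
  }
  hub_taxa <- vapply(groups[vapply(groups, function(g) g$type == "hub_group",
                                   logical(1))],
                     function(g) g$taxa[1L], character(1))
  indicators <- cfg$indicators
  for (k in seq_along(indicators)) {
    cursor <- cursor + 1L
    indicators[[k]]$taxon_id <- taxa[cursor]
  }

  # --- latent log-abundances ---
  base <- stats::rnorm(n_taxa, cfg$base_abundance[1], cfg$base_abundance[2])
  # planted module/hub taxa sit in the moderately abundant part of the
  # community: correlation structure is only detectable for taxa sampled
  # with adequate counts, and empirical keystone taxa are never singletons
  planted_idx <- match(unlist(lapply(groups, `[[`, "taxa")), taxa)
  if (length(planted_idx)) {
    base[planted_idx] <- stats::rnorm(length(planted_idx),
                                      cfg$planted_base[1],
                                      cfg$planted_base[2])
  }
  eps <- matrix(stats::rnorm(n_taxa * n_samples), n_taxa, n_samples)
  u <- eps
  for (g in groups) {
    ss <- which(stratum == g$stratum)
    if (!length(ss)) next
    z <- stats::rnorm(length(ss))
    ti <- match(g$taxa, taxa)
    u[ti, ss] <- g$loading * matrix(z, length(ti), length(ss), byrow = TRUE) +
      sqrt(1 - g$loading^2) * eps[ti, ss]
  }
  eta <- base + u # base recycles down columns
  for (ind in indicators) {
    ss <- which(stratum %in% ind$combo)
    eta[match(ind$taxon_id, taxa), ss] <-
      eta[match(ind$taxon_id, taxa), ss] + ind$lfc
  }

  # --- relative abundances and Dirichlet-multinomial counts ---
  rel <- apply(eta, 2L, function(col) {
    e <- exp(col - max(col))
    e / sum(e)
  })
  depth <- pmax(1000L,
                as.integer(round(stats::rlnorm(n_samples,
                                               log(cfg$depth_mean),
                                               cfg$depth_sd))))
  counts <- vapply(seq_len(n_samples), function(s) {
    a <- rel[, s] * cfg$overdispersion
    gdraw <- stats::rgamma(n_taxa, shape = a, rate = 1)
    if (sum(gdraw) == 0) gdraw <- rel[, s]
    as.integer(stats::rmultinom(1L, depth[s], gdraw / sum(gdraw)))
  }, integer(n_taxa))
  dimnames(counts) <- list(taxa, meta$sample_id)

  # --- tree and guilds ---
  tree <- ape::rtree(n_taxa, tip.label = taxa, br = stats::rexp)
  fr <- cfg$guild_fractions
  guild_labels <- sample(c(names(fr), "unassigned"), n_taxa, replace = TRUE,
                         prob = c(fr, 1 - sum(fr)))
  guilds <- data.frame(taxon_id = taxa, kingdom = cfg$kingdom,
                       guild = guild_labels, stringsAsFactors = FALSE)

  # --- ground truth ---
  strata_u <- sort(unique(stratum))
  mean_rel <- vapply(strata_u, function(s) {
    rowMeans(rel[, stratum == s, drop = FALSE])
  }, numeric(n_taxa))
  rownames(mean_rel) <- taxa
  truth <- list(
    groups = lapply(groups, function(g) {
      g[c("type", "stratum", "loading", "taxa")]
    }),
    hub_taxa = unname(hub_taxa),
    hub_strata = vapply(groups[vapply(groups,
                                      function(g) g$type == "hub_group",
                                      logical(1))],
                        function(g) g$stratum, character(1)),
    indicators = if (length(indicators)) {
      data.frame(
        taxon_id = vapply(indicators, `[[`, character(1), "taxon_id"),
        combo = vapply(indicators,
                       function(i) paste(sort(i$combo), collapse = "+"),
                       character(1)),
        lfc = vapply(indicators, `[[`, numeric(1), "lfc"),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(taxon_id = character(0), combo = character(0),
                 lfc = numeric(0))
    },
    stratum_mean_relabund = mean_rel
  )

  structure(list(counts = count_matrix(counts), metadata = meta, tree = tree,
                 guilds = guilds, truth = truth, config = cfg),
            class = "community_simulation")
}

#' Scenario presets
#'
#' - `orchard_benchmark`: the full 5-stratum design (IPM/organic x
#'   crop/drive rows + semi-natural grassland, 90 samples each, 450 total);
#'   the grassland stratum carries 10 hub groups (hub + 9 partners, loading
#'   0.92) so its network is densely connected, each orchard stratum one
#'   6-taxon module at loading 0.85 (planted degree 5, deliberately below
#'   the fungal keystone degree cutoff), and 20 indicator taxa (15
#'   single-stratum, 5 two-stratum combos) at log-fold-change 2.
#' - `null_community`: one 60-sample stratum with no planted structure, for
#'   false-positive calibration.
#' - `tiny_fixture`: 12 taxa, 10 samples, runs the full pipeline in
#'   seconds.
#'
#' @param name preset name.
#' @param seed seed stored in the returned config.
#' @return a [simulation_config()].
#' @export
scenario_preset <- function(name = c("orchard_benchmark", "null_community",
                                     "tiny_fixture"), seed = 1L) {
  if (!is.character(name) || !name[1L] %in% c("orchard_benchmark",
                                              "null_community",
                                              "tiny_fixture")) {
    abort("unknown preset '%s'; available: orchard_benchmark, null_community, tiny_fixture",
          as.character(name[1L]))
  }
  name <- name[1L]
  orchard_strata <- data.frame(
    land_use = c("IPM", "IPM", "organic", "organic", "grassland"),
    location = c("crop_row", "drive_row", "crop_row", "drive_row", "none"),
    n_samples = 90L, stringsAsFactors = FALSE
  )
  switch(name,
    orchard_benchmark = {
      orchard_names <- c("IPM_crop_row", "IPM_drive_row",
                         "organic_crop_row", "organic_drive_row")
      singles <- rep(c(orchard_names, "grassland"), each = 3L)
      pairs <- list(
        c("IPM_crop_row", "IPM_drive_row"),
        c("organic_crop_row", "organic_drive_row"),
        c("IPM_drive_row", "organic_drive_row"),
        c("grassland", "organic_drive_row"),
        c("IPM_crop_row", "organic_crop_row")
      )
      indicators <- c(
        lapply(singles, function(s) list(combo = s, lfc = 2)),
        lapply(pairs, function(p) list(combo = p, lfc = 2))
      )
      simulation_config(
        n_taxa = 200L, strata = orchard_strata,
        depth_mean = 20000, depth_sd = 0.15,
        modules = lapply(orchard_names, function(s) {
          list(taxon_count = 6L, loading = 0.88, stratum = s)
        }),
        hubs = replicate(10L, list(partners = 9L, loading = 0.95,
                                   stratum = "grassland"), simplify = FALSE),
        indicators = indicators,
        kingdom = "fungi", seed = seed
      )
    },
    null_community = simulation_config(
      n_taxa = 40L,
      strata = data.frame(land_use = "grassland", location = "none",
                          n_samples = 60L, stringsAsFactors = FALSE),
      depth_mean = 5000, depth_sd = 0.2, overdispersion = 200,
      kingdom = "fungi", seed = seed
    ),
    tiny_fixture = simulation_config(
      n_taxa = 12L,
      strata = data.frame(land_use = c("IPM", "grassland"),
                          location = c("drive_row", "none"),
                          n_samples = 5L, stringsAsFactors = FALSE),
      depth_mean = 2000, depth_sd = 0.1,
      modules = list(list(taxon_count = 4L, loading = 0.9,
                          stratum = "grassland")),
      indicators = list(list(combo = "grassland", lfc = 2),
                        list(combo = "IPM_drive_row", lfc = 2)),
      overdispersion = 300, kingdom = "fungi", seed = seed
    )
  )
}

#' Serialize a simulation to disk
#'
#' Writes counts.tsv, metadata.tsv, tree.nwk, guilds.tsv and
#' ground_truth.json into a directory, the plain-text artifact set the rest
#' of the pipeline consumes.
#'
#' @param sim a `community_simulation`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "community_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    tree = file.path(dir, "tree.nwk"),
    guilds = file.path(dir, "guilds.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_count_table(sim$counts, paths["counts"])
  write_sample_metadata(sim$metadata, paths["metadata"])
  write_newick(sim$tree, paths["tree"])
  write_guild_table(sim$guilds, paths["guilds"])
  truth <- sim$truth
  truth$stratum_mean_relabund <- NULL # large; recomputable from the config
  jsonlite::write_json(truth, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
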