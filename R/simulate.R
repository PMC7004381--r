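#' Simulation configuration for multi-study community data
#'
#' Defaults emulate the structure of a seven-study host-vs-water survey:
#' per study, a long-tailed (log-normal) water source community over a
#' shared taxon namespace, a host community assembled as a selected,
#' lower-richness subset of that water community, planted core taxa
#' elevated relative to the typical retained taxon across (almost) all
#' studies, planted host-enriched and water-only taxa, variable
#' sequencing depth and Dirichlet-multinomial replicate noise.
#'
#' @param n_studies number of studies (default 7).
#' @param n_background background taxa (default 80).
#' @param n_core planted core taxa (default 5).
#' @param core_log2_boost core elevation over the typical retained
#'   taxon, log2 units (default 2).
#' @param n_host_samples,n_water_samples samples per study (default 10
#'   each).
#' @param selection_sparsity fraction of taxa excluded from host
#'   communities per study (default 0.5); half the quota is a fixed
#'   water-only set, the rest is redrawn per study.
#' @param n_enriched_host planted host-enriched taxa (default 5).
#' @param enrichment_log2 host-vs-water log2 enrichment (default 2),
#'   planted as a depletion of those taxa in the water composition.
#' @param depth_range min/max reads per sample (default 10000-30000).
#' @param overdispersion Dirichlet concentration multiplier for
#'   replicate noise (default 200; larger = less sample-to-sample
#'   variation).
#' @param baseline_sigma log-normal sd (natural log) of the water
#'   rank-abundance distribution (default 1.5).
#' @param seed master seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_studies = 7L, n_background = 80L, n_core = 5L,
                       core_log2_boost = 2.0, n_host_samples = 10L,
                       n_water_samples = 10L, selection_sparsity = 0.5,
                       n_enriched_host = 5L, enrichment_log2 = 2.0,
                       depth_range = c(10000L, 30000L),
                       overdispersion = 200, baseline_sigma = 1.5,
                       seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              n_background = as.integer(n_background),
              n_core = as.integer(n_core),
              core_log2_boost = core_log2_boost,
              n_host_samples = as.integer(n_host_samples),
              n_water_samples = as.integer(n_water_samples),
              selection_sparsity = selection_sparsity,
              n_enriched_host = as.integer(n_enriched_host),
              enrichment_log2 = enrichment_log2,
              depth_range = as.integer(depth_range),
              overdispersion = overdispersion,
              baseline_sigma = baseline_sigma,
              seed = as.integer(seed))
  cfg$taxa_total <- cfg$n_background + cfg$n_core + cfg$n_enriched_host
  if (cfg$n_studies < 2L) stop("invalid 'n_studies': need >= 2")
  if (cfg$n_core < 0L || cfg$n_core > cfg$taxa_total) {
    stop("invalid 'n_core'")
  }
  if (cfg$selection_sparsity < 0 || cfg$selection_sparsity >= 1) {
    stop("invalid 'selection_sparsity': must be in [0, 1)")
  }
  if (length(cfg$depth_range) != 2L || any(cfg$depth_range <= 0) ||
      cfg$depth_range[1] > cfg$depth_range[2]) {
    stop("invalid 'depth_range'")
  }
  if (cfg$overdispersion <= 0) stop("invalid 'overdispersion'")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a random rooted phylogeny
#'
#' Random rooted binary topology by sequential random coalescence with
#' independent exponential (rate 1) branch lengths; deterministic given
#' the seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param tip_labels optional tip names (default `t1..tn`).
#' @return an `ape` `phylo` tree.
#' @export
simulate_tree <- function(n_tips, seed = 1L, tip_labels = NULL) {
  if (n_tips < 2L) stop("'n_tips' must be >= 2")
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n_tips))
  with_seed(seed, {
    tr <- ape::rcoal(n_tips, tip.label = tip_labels)
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1)
    tr
  })
}

# one Dirichlet-multinomial sample: composition p, concentration c, depth n
rdirmult <- function(p, concentration, depth) {
  alpha <- p * concentration
  g <- stats::rgamma(length(p), shape = alpha)
  if (sum(g) == 0) g[which.max(p)] <- 1
  as.integer(stats::rmultinom(1L, depth, g / sum(g)))
}

#' Simulate a multi-study host/water community data set
#'
#' Per study: the water baseline composition is drawn log-normally over
#' the shared taxon namespace; the host composition applies selection
#' weights (a `selection_sparsity` fraction of taxa excluded: a fixed
#' water-only set plus a per-study random remainder), sets each planted
#' core taxon to `2^core_log2_boost` times the median retained
#' background abundance, and leaves host-enriched taxa at their baseline
#' draw while depleting them `2^-enrichment_log2`-fold in the water
#' composition. Counts are Dirichlet-multinomial at a per-sample depth
#' uniform in `depth_range`. Core taxa are protected from host
#' selection (boosted in every study); enriched and background taxa
#' share the stochastic per-study exclusion quota, so cross-study
#' presence varies and the prevalence rule does real filtering work.
#' All planted sets are recorded as ground truth before any sampling
#' noise.
#'
#' @param config a [sim_config()].
#' @return object of class `multistudy_sim`: list with `collection`
#'   (host [study_collection()]), `water_tables` (named list),
#'   `metadata` (data.frame), `tree` (`phylo`), `truth` (list:
#'   `core_taxa`, `host_enriched`, `water_only`, `baselines`,
#'   `selection`) and `config`.
#' @export
simulate_multistudy <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  nt <- cfg$taxa_total
  taxa <- sprintf("taxon%03d", seq_len(nt))
  core <- taxa[seq_len(cfg$n_core)]
  enriched <- taxa[cfg$n_core + seq_len(cfg$n_enriched_host)]
  background <- setdiff(taxa, c(core, enriched))
  seeds <- derive_seeds(cfg$seed, cfg$n_studies + 2L)
  tree <- simulate_tree(nt, seed = seeds[cfg$n_studies + 1L],
                        tip_labels = taxa)

  sim <- with_seed(seeds[cfg$n_studies + 2L], {
    n_excl <- round(cfg$selection_sparsity * nt)
    # a small fixed set of water specialists is always excluded from the
    # host; the rest of the exclusion quota is redrawn per study, so
    # cross-study presence of ordinary taxa is stochastic
    n_fixed <- min(max(0L, round(nt / 9)), length(background), n_excl)
    water_only <- sort(sample(background, n_fixed))
    list(water_only = water_only, n_excl = n_excl)
  })
  water_only <- sim$water_only

  host_tables <- list()
  water_tables <- list()
  meta <- list()
  baselines <- matrix(NA_real_, nt, cfg$n_studies,
                      dimnames = list(taxa, NULL))
  selection <- matrix(NA_real_, nt, cfg$n_studies,
                      dimnames = list(taxa, NULL))

  for (s in seq_len(cfg$n_studies)) {
    study_id <- sprintf("study%d", s)
    tabs <- with_seed(seeds[s], {
      base <- stats::setNames(
        stats::rlnorm(nt, meanlog = 0, sdlog = cfg$baseline_sigma), taxa)
      water_comp <- base
      water_comp[enriched] <- water_comp[enriched] * 2^(-cfg$enrichment_log2)
      water_comp <- water_comp / sum(water_comp)

      # per-study host selection: core taxa are protected; enriched and
      # background taxa share the stochastic exclusion quota
      sel <- stats::setNames(rep(1, nt), taxa)
      sel[water_only] <- 0
      extra_pool <- setdiff(c(background, enriched), water_only)
      n_extra <- max(0L, sim$n_excl - length(water_only))
      if (n_extra > 0L) sel[sample(extra_pool, n_extra)] <- 0

      host_comp <- base * sel
      retained_bg <- intersect(background, names(sel)[sel > 0])
      typical <- stats::median(host_comp[retained_bg])
      host_comp[core] <- typical * 2^cfg$core_log2_boost
      host_comp <- host_comp / sum(host_comp)

      draw_table <- function(comp, n_samp, prefix) {
        depths <- sample(seq(cfg$depth_range[1], cfg$depth_range[2]),
                         n_samp, replace = TRUE)
        m <- vapply(seq_len(n_samp), function(i) {
          rdirmult(comp, cfg$overdispersion, depths[i])
        }, integer(nt))
        dimnames(m) <- list(taxa, paste0(prefix, seq_len(n_samp)))
        feature_table(m)
      }
      list(host = draw_table(host_comp, cfg$n_host_samples,
                             paste0(study_id, "_DAB")),
           water = draw_table(water_comp, cfg$n_water_samples,
                              paste0(study_id, "_AW")),
           base = base, sel = sel)
    })
    host_tables[[study_id]] <- tabs$host
    water_tables[[study_id]] <- tabs$water
    baselines[, s] <- tabs$base
    selection[, s] <- tabs$sel
    meta[[study_id]] <- data.frame(
      sample_id = c(colnames(tabs$host), colnames(tabs$water)),
      study = study_id,
      community_type = rep(c("DAB", "AW"),
                           c(cfg$n_host_samples, cfg$n_water_samples)),
      timepoint = 0,
      host = rep(c("Lemna_minor", "none"),
                 c(cfg$n_host_samples, cfg$n_water_samples)),
      treatment = "none",
      compartment = "whole",
      pair_id = "",
      stringsAsFactors = FALSE
    )
  }
  colnames(baselines) <- colnames(selection) <- names(host_tables)

  structure(list(
    collection = study_collection(host_tables),
    water_tables = water_tables,
    metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    tree = tree,
    truth = list(core_taxa = core, host_enriched = enriched,
                 water_only = water_only,
                 baselines = baselines, selection = selection),
    config = cfg
  ), class = "multistudy_sim")
}

#' @export
print.multistudy_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("multistudy_sim: %d studies, %d taxa ",
                     "(%d core, %d host-enriched, %d water-only), ",
                     "%d host + %d water samples per study\n"),
              cfg$n_studies, cfg$taxa_total, cfg$n_core,
              cfg$n_enriched_host, length(x$truth$water_only),
              cfg$n_host_samples, cfg$n_water_samples))
  invisible(x)
}

#' Write the full simulated fixture set to a directory
#'
#' Emits host and water tables (TSV), sample metadata (TSV), the tree
#' (newick), the ground truth (JSON) and a config echo (JSON).
#'
#' @param sim a `multistudy_sim`.
#' @param dir output directory (created if needed).
#' @export
write_multistudy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$collection$studies)) {
    write_feature_table(sim$collection$studies[[s]],
                        file.path(dir, paste0(s, "_host.tsv")))
    write_feature_table(sim$water_tables[[s]],
                        file.path(dir, paste0(s, "_water.tsv")))
  }
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  truth <- sim$truth
  truth$baselines <- as.data.frame(truth$baselines)
  truth$selection <- as.data.frame(truth$selection)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(dir, "metadata.tsv"), "simulate_multistudy",
                   list(seed = sim$config$seed))
  invisible(dir)
}
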