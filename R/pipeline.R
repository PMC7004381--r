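#' Pipeline configuration
#'
#' Declarative configuration for the full analysis run. Defaults mirror
#' the analysis parameters used throughout the package: survey
#' rarefaction depth 3664, significance threshold 0.05, effect-size
#' threshold 1.5, core fold threshold 1 (log2) in at least 6 studies,
#' generalized-UniFrac alpha 0.5, 128 Monte-Carlo clr instances.
#'
#' @param input_dir optional directory of tables as written by
#'   [write_multistudy()]; when NULL the pipeline simulates its input
#'   with [simulate_multistudy()].
#' @param output_dir directory for artifacts.
#' @param rarefaction_depth survey depth (default 3664).
#' @param collapse_rank rank for taxonomic collapsing where a taxonomy
#'   is available (default "genus"; simulated taxa are already
#'   genus-like units).
#' @param gunifrac_alpha generalized-UniFrac alpha (default 0.5).
#' @param n_instances Monte-Carlo clr instances (default 128).
#' @param p_threshold,effect_threshold significance rule (0.05, 1.5).
#' @param fold_threshold,min_studies core rule (1.0, 6).
#' @param prevalence_boundary prevalence class boundary (0.25).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param seeds named list of per-stage seeds (simulation, rarefaction,
#'   clr, permanova, dunnett); missing entries are derived from `seed`.
#' @param seed master seed used to fill unspecified stage seeds.
#' @param sim a [sim_config()] used when simulating input.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = "coremicro_out",
                            rarefaction_depth = 3664L,
                            collapse_rank = "genus",
                            gunifrac_alpha = 0.5, n_instances = 128L,
                            p_threshold = 0.05, effect_threshold = 1.5,
                            fold_threshold = 1.0, min_studies = 6L,
                            prevalence_boundary = 0.25,
                            n_permutations = 999L, seeds = list(),
                            seed = 1L, sim = NULL) {
  if (rarefaction_depth <= 0) stop("invalid 'rarefaction_depth'")
  if (p_threshold <= 0 || effect_threshold <= 0 || fold_threshold <= 0) {
    stop("thresholds must be positive")
  }
  if (gunifrac_alpha < 0 || gunifrac_alpha > 1) stop("invalid 'gunifrac_alpha'")
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input directory not found: ", input_dir)
  }
  stage_names <- c("simulation", "rarefaction", "clr", "permanova", "dunnett")
  derived <- derive_seeds(seed, length(stage_names))
  for (i in seq_along(stage_names)) {
    if (is.null(seeds[[stage_names[i]]])) seeds[[stage_names[i]]] <- derived[i]
  }
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 rarefaction_depth = as.integer(rarefaction_depth),
                 collapse_rank = collapse_rank,
                 gunifrac_alpha = gunifrac_alpha,
                 n_instances = as.integer(n_instances),
                 p_threshold = p_threshold,
                 effect_threshold = effect_threshold,
                 fold_threshold = fold_threshold,
                 min_studies = as.integer(min_studies),
                 prevalence_boundary = prevalence_boundary,
                 n_permutations = as.integer(n_permutations),
                 seeds = lapply(seeds, as.integer),
                 sim = if (is.null(sim)) sim_config(seed = seeds$simulation)
                       else sim),
            class = "pipeline_config")
}

read_multistudy_dir <- function(dir) {
  hosts <- sort(list.files(dir, pattern = "_host\\.tsv$", full.names = TRUE))
  waters <- sort(list.files(dir, pattern = "_water\\.tsv$", full.names = TRUE))
  if (!length(hosts)) stop("no *_host.tsv tables found in ", dir)
  study_ids <- sub("_host\\.tsv$", "", basename(hosts))
  host_tables <- stats::setNames(lapply(hosts, read_feature_table), study_ids)
  water_tables <- stats::setNames(lapply(waters, read_feature_table),
                                  sub("_water\\.tsv$", "", basename(waters)))
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  tree_path <- file.path(dir, "tree.nwk")
  tree <- if (file.exists(tree_path)) ape::read.tree(tree_path) else NULL
  list(collection = study_collection(host_tables),
       water_tables = water_tables, metadata = meta, tree = tree)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on either a directory of
#' input tables or a freshly simulated multi-study data set: per-study
#' host-vs-water diversity (observed features, Faith's PD, Bray-Curtis,
#' Jaccard, unweighted and generalized UniFrac, PCoA, PERMANOVA),
#' rarefaction of the first study, clr differential abundance
#' host-vs-water with the significance rule, and the cross-study core
#' selection. Every artifact is written with a provenance sidecar;
#' the returned (and saved) manifest lists artifact paths, md5 hashes
#' and summary statistics. Identical configuration and seeds give
#' identical manifest hashes.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging (default FALSE).
#' @return the manifest (list), invisibly written to
#'   `<output_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must be a pipeline_config")
  }
  log_stage <- function(...) if (!quiet) message("[coremicro] ", ...)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  summaries <- list()
  add_artifact <- function(name, path) {
    artifacts[[name]] <<- list(path = path,
                               md5 = unname(tools::md5sum(path)))
  }

  # --- input -------------------------------------------------------------
  if (is.null(config$input_dir)) {
    log_stage("simulate: ", config$sim$n_studies, " studies, seed ",
              config$seeds$simulation)
    simc <- config$sim
    simc$seed <- config$seeds$simulation
    data <- simulate_multistudy(simc)
  } else {
    log_stage("load: ", config$input_dir)
    data <- read_multistudy_dir(config$input_dir)
  }
  studies <- data$collection$studies
  first_id <- names(studies)[1L]

  # --- per-study host vs water diversity --------------------------------
  study1 <- cbind(unclass(studies[[first_id]]),
                  unclass(data$water_tables[[first_id]]))
  study1 <- feature_table(study1)
  groups <- stats::setNames(
    data$metadata$community_type[match(colnames(study1),
                                       data$metadata$sample_id)],
    colnames(study1))
  log_stage("alpha diversity on ", first_id, " (",
            ncol(study1), " samples)")
  obs <- observed_features(study1)
  alpha_df <- data.frame(sample_id = names(obs), observed = obs,
                         row.names = NULL)
  if (!is.null(data$tree)) {
    alpha_df$faith_pd <- faith_pd(study1, data$tree)[alpha_df$sample_id]
  }
  apath <- file.path(out, "alpha_diversity.tsv")
  utils::write.table(alpha_df, apath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_provenance(apath, "alpha_diversity", list(study = first_id))
  add_artifact("alpha_diversity", apath)
  summaries$mean_observed_host <- mean(obs[groups == "DAB"])
  summaries$mean_observed_water <- mean(obs[groups == "AW"])

  log_stage("beta diversity + ordination + permanova")
  dms <- list(bray_curtis = bray_curtis(study1), jaccard = jaccard(study1))
  if (!is.null(data$tree)) {
    dms$unweighted_unifrac <- unweighted_unifrac(study1, data$tree)
    dms$generalized_unifrac <-
      generalized_unifrac(study1, data$tree, alpha = config$gunifrac_alpha)
  }
  for (nm in names(dms)) {
    p <- file.path(out, paste0("beta_", nm, ".tsv"))
    write_distance_matrix(dms[[nm]], p)
    add_artifact(paste0("beta_", nm), p)
  }
  ord <- pcoa(dms$bray_curtis)
  write_ordination(ord, file.path(out, "pcoa_bray_curtis"))
  add_artifact("pcoa_coords", file.path(out, "pcoa_bray_curtis_coords.tsv"))
  perm <- permanova(dms$bray_curtis, groups,
                    n_permutations = config$n_permutations,
                    seed = config$seeds$permanova)
  ppath <- file.path(out, "permanova_host_vs_water.json")
  write_permanova(perm, ppath)
  add_artifact("permanova", ppath)
  summaries$permanova_pseudo_F <- perm$pseudo_F
  summaries$permanova_p <- perm$p_value

  # --- rarefaction -------------------------------------------------------
  depth <- min(config$rarefaction_depth, min(colSums(study1)))
  log_stage("rarefy ", first_id, " to depth ", depth)
  rar <- rarefy(study1, depth, seed = config$seeds$rarefaction)
  rpath <- file.path(out, "rarefied.tsv")
  write_feature_table(rar, rpath)
  add_artifact("rarefied", rpath)
  summaries$rarefaction_depth <- depth
  summaries$rarefaction_dropped <- length(attr(rar, "dropped"))

  # --- differential abundance host vs water -----------------------------
  log_stage("clr + differential abundance host vs water")
  nonzero <- study1[rowSums(study1) > 0, , drop = FALSE]
  clr <- clr_transform(nonzero, n_instances = config$n_instances,
                       seed = config$seeds$clr)
  da <- diff_abund_pairwise(clr, groups, seed = config$seeds$clr)
  dpath <- file.path(out, "diff_abund_host_vs_water.tsv")
  write_diff_abund(da, dpath)
  add_artifact("diff_abund", dpath)
  sig <- significant_taxa(da, config$p_threshold, config$effect_threshold)
  summaries$n_significant_taxa <- nrow(sig)

  # --- cross-study core selection ---------------------------------------
  log_stage("core selection across ", length(studies), " studies")
  core <- select_core(data$collection, min_studies = config$min_studies,
                      fold_threshold = config$fold_threshold,
                      n_instances = config$n_instances,
                      seed = config$seeds$clr)
  write_core_result(core, file.path(out, "core_result"))
  add_artifact("core_result", file.path(out, "core_result.tsv"))
  summaries$n_candidates <- length(core$candidates)
  summaries$n_core_taxa <- length(core$core_taxa)

  manifest <- list(
    config = list(rarefaction_depth = config$rarefaction_depth,
                  gunifrac_alpha = config$gunifrac_alpha,
                  n_instances = config$n_instances,
                  p_threshold = config$p_threshold,
                  effect_threshold = config$effect_threshold,
                  fold_threshold = config$fold_threshold,
                  min_studies = config$min_studies,
                  n_permutations = config$n_permutations,
                  seeds = config$seeds),
    artifacts = artifacts,
    summaries = summaries
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done: ", length(artifacts), " artifacts in ", out)
  invisible(manifest)
}
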