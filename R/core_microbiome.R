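#' Construct a multi-study collection
#'
#' A named list of feature tables, one per study, all collapsed to the
#' same taxonomic rank over a shared taxon namespace and restricted to
#' the host-associated samples of each study.
#'
#' @param tables named list of feature tables (names = study ids).
#' @return object of class `study_collection`.
#' @export
study_collection <- function(tables) {
  if (!length(tables)) stop("empty study collection")
  if (is.null(names(tables)) || anyDuplicated(names(tables)) ||
      any(names(tables) == "")) {
    stop("studies must have unique non-empty names")
  }
  tables <- lapply(tables, as_feature_table)
  empty <- vapply(tables, function(t) nrow(t) == 0L || ncol(t) == 0L,
                  logical(1))
  if (any(empty)) stop("empty study tables: ",
                       paste(names(tables)[empty], collapse = ", "))
  structure(list(studies = tables), class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf("study_collection: %d studies (%s)\n", length(x$studies),
              paste(names(x$studies), collapse = ", ")))
  invisible(x)
}

# taxa observed (count > 0 in >= 1 sample, or in >= min_sample_fraction
# of samples) in one study table
study_presence <- function(table, min_sample_fraction = 0) {
  frac <- rowSums(unclass(table) > 0) / ncol(table)
  rownames(table)[if (min_sample_fraction > 0) frac >= min_sample_fraction
                  else frac > 0]
}

#' Candidate core taxa by cross-study prevalence
#'
#' Taxa present in at least `min_studies` studies. "Present in a study"
#' defaults to nonzero in at least one sample; `min_sample_fraction`
#' optionally requires presence in that fraction of the study's samples.
#'
#' @param collection a `study_collection`.
#' @param min_studies integer between 1 and the number of studies.
#' @param min_sample_fraction optional within-study prevalence cutoff.
#' @return character vector of candidate taxa.
#' @export
candidate_core_taxa <- function(collection, min_studies,
                                min_sample_fraction = 0) {
  ns <- length(collection$studies)
  if (min_studies < 1L || min_studies > ns) {
    stop("'min_studies' must be between 1 and the number of studies")
  }
  pres <- lapply(collection$studies, study_presence, min_sample_fraction)
  counts <- table(unlist(pres, use.names = FALSE))
  sort(names(counts)[counts >= min_studies])
}

#' Core score of a taxon within one study
#'
#' Delta = median clr of the taxon over the study's samples minus the
#' median clr of the pooled non-core community (all (taxon, sample,
#' instance) clr values of every non-candidate taxon). Units are log2
#' fold (a difference of log2-scale clr values); negative values mean
#' the taxon sits below the non-core community abundance.
#'
#' @param clr a `clr_distribution` for the study (observed taxa only).
#' @param taxon candidate taxon id.
#' @param candidates character vector of candidate taxa.
#' @return a single numeric Delta in log2 units.
#' @export
core_score <- function(clr, taxon, candidates) {
  if (!taxon %in% candidates) stop("'taxon' must be one of the candidates")
  noncore <- setdiff(clr$feature_ids, candidates)
  if (!length(noncore)) stop("non-core community is empty in this study")
  median_clr(clr, features = taxon) - median_clr(clr, features = noncore)
}

#' Cross-study core-microbiome selection
#'
#' Runs the full core-identification procedure: candidate taxa are those
#' present in at least `min_studies` studies; within each study the clr
#' distribution is computed on that study's observed taxa and each
#' candidate's Delta against the pooled non-core community median is
#' recorded; core taxa are candidates whose Delta exceeds
#' `fold_threshold` (log2 units) in at least `min_studies` studies.
#' Taxa absent from a study contribute no Delta there and that study
#' cannot count toward `min_studies`. Optionally a Monte-Carlo Dunnett
#' test compares each core taxon's per-sample median clr (pooled across
#' studies) against the pooled non-core per-sample medians.
#'
#' @param collection a `study_collection`.
#' @param min_studies default 6.
#' @param fold_threshold default 1.0 (the 2-fold, log2 > 1 rule).
#' @param min_sample_fraction optional within-study prevalence cutoff
#'   for candidacy.
#' @param n_instances Monte-Carlo instances per study clr (default 128).
#' @param seed integer seed.
#' @param dunnett compute Dunnett p-values for the core taxa
#'   (default TRUE).
#' @return object of class `core_result`: list with `candidates`,
#'   `per_study_delta` (taxa x studies, NA where absent),
#'   `noncore_median` (per study), `core_taxa`, `dunnett_p`.
#' @export
select_core <- function(collection, min_studies = 6L, fold_threshold = 1.0,
                        min_sample_fraction = 0, n_instances = 128L,
                        seed = 1L, dunnett = TRUE) {
  studies <- collection$studies
  ns <- length(studies)
  candidates <- candidate_core_taxa(collection, min_studies,
                                    min_sample_fraction)
  seeds <- derive_seeds(seed, ns + 1L)
  delta <- matrix(NA_real_, nrow = length(candidates), ncol = ns,
                  dimnames = list(candidates, names(studies)))
  noncore_median <- stats::setNames(rep(NA_real_, ns), names(studies))
  core_samples <- list()   # per-sample median clr per core-candidate taxon
  control_samples <- list()

  for (s in seq_len(ns)) {
    tab <- studies[[s]]
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]  # the study's observed taxa
    clr <- clr_transform(tab, n_instances = n_instances, seed = seeds[s])
    noncore <- setdiff(clr$feature_ids, candidates)
    if (!length(noncore)) {
      stop("non-core community empty in study '", names(studies)[s], "'")
    }
    nc_med <- median_clr(clr, features = noncore)
    noncore_median[s] <- nc_med
    present <- intersect(candidates, clr$feature_ids)
    if (length(present)) {
      taxon_med <- feature_median_clr(clr_subset(clr, features = present))
      delta[present, s] <- taxon_med - nc_med
    }
    med_fs <- sample_median_clr(clr)  # features x samples
    for (t in present) {
      core_samples[[t]] <- c(core_samples[[t]], med_fs[t, ])
    }
    control_samples[[s]] <- apply(med_fs[noncore, , drop = FALSE], 2L,
                                  stats::median)
  }

  n_pass <- rowSums(delta > fold_threshold, na.rm = TRUE)
  core_taxa <- candidates[n_pass >= min_studies]

  dunnett_p <- NULL
  if (dunnett && length(core_taxa)) {
    groups <- core_samples[core_taxa]
    control <- unlist(control_samples, use.names = FALSE)
    dunnett_p <- dunnett_test(groups, control, seed = seeds[ns + 1L])
  }

  structure(list(candidates = candidates,
                 per_study_delta = delta,
                 noncore_median = noncore_median,
                 core_taxa = core_taxa,
                 n_studies_passing = n_pass,
                 fold_threshold = fold_threshold,
                 min_studies = as.integer(min_studies),
                 dunnett_p = dunnett_p),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf("core_result: %d candidates, %d core taxa (log2 > %g in >= %d studies)\n",
              length(x$candidates), length(x$core_taxa),
              x$fold_threshold, x$min_studies))
  if (length(x$core_taxa)) cat("core:", paste(x$core_taxa, collapse = ", "), "\n")
  invisible(x)
}

#' Write a core result as a heat-map style TSV plus JSON
#'
#' The TSV mirrors a taxa x studies layout of Delta values with the
#' per-study non-core medians and core membership flags appended.
#'
#' @param result a `core_result`.
#' @param prefix path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @export
write_core_result <- function(result, prefix) {
  tsv <- paste0(prefix, ".tsv")
  df <- data.frame(taxon = rownames(result$per_study_delta),
                   result$per_study_delta,
                   n_studies_passing = result$n_studies_passing,
                   core = rownames(result$per_study_delta) %in% result$core_taxa,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- result
  payload$per_study_delta <- as.data.frame(result$per_study_delta)
  jsonlite::write_json(unclass(payload), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  write_provenance(tsv, "write_core_result",
                   list(fold_threshold = result$fold_threshold,
                        min_studies = result$min_studies))
  invisible(prefix)
}

#' Many-to-one Dunnett comparisons by Monte-Carlo max-|t|
#'
#' Compares each treatment group's mean against a shared control under
#' equal-variance normality. The familywise-adjusted p-value of each
#' comparison is the probability, under the null, that the maximum
#' absolute Dunnett t-statistic across all comparisons exceeds the
#' observed one, estimated by seeded Monte-Carlo simulation of the
#' group means and the pooled variance.
#'
#' @param groups named list of numeric vectors (treatment groups).
#' @param control numeric vector (control group, length >= 2).
#' @param n_draws Monte-Carlo draws for the max-|t| null (default 1e5).
#' @param seed integer seed.
#' @return named numeric vector of adjusted p-values, one per group.
#' @export
dunnett_test <- function(groups, control, n_draws = 1e5, seed = 1L) {
  if (!length(groups)) stop("need at least one treatment group")
  if (length(control) < 2L) stop("control group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  n0 <- length(control)
  ni <- vapply(groups, length, integer(1))
  if (any(ni < 2L)) stop("every treatment group needs >= 2 values")
  all_vals <- c(list(control), groups)
  ss <- sum(vapply(all_vals, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- sum(vapply(all_vals, length, integer(1))) - (k + 1L)
  if (ss == 0) stop("zero within-group variance; Dunnett t undefined")
  s2 <- ss / df
  t_obs <- vapply(seq_len(k), function(i) {
    (mean(groups[[i]]) - mean(control)) / sqrt(s2 * (1 / ni[i] + 1 / n0))
  }, numeric(1))

  p <- with_seed(seed, {
    b <- as.integer(n_draws)
    z0 <- stats::rnorm(b, sd = sqrt(1 / n0))
    s2_null <- stats::rchisq(b, df) / df
    maxt <- rep(0, b)
    for (i in seq_len(k)) {
      zi <- stats::rnorm(b, sd = sqrt(1 / ni[i]))
      ti <- abs(zi - z0) / sqrt(s2_null * (1 / ni[i] + 1 / n0))
      maxt <- pmax(maxt, ti)
    }
    vapply(abs(t_obs), function(t) mean(maxt >= t), numeric(1))
  })
  stats::setNames(p, names(groups))
}
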