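#' Categorize features by prevalence, abundance and source community
#'
#' For each feature present in the focal community: a prevalence class
#' from the fraction of focal samples with count > 0 (strictly more than
#' the boundary, default 25%, is "high"); an abundance class from the
#' median clr over the focal samples and instances (strictly above the
#' threshold, default 0, is "high"); and flags marking every labelled
#' community the feature was observed in.
#'
#' @param clr a `clr_distribution` covering at least the focal samples.
#' @param table feature table covering all labelled communities.
#' @param communities named vector mapping each sample of `table` to a
#'   community label.
#' @param focal the focal community label.
#' @param prevalence_boundary fraction boundary (default 0.25; exactly at
#'   the boundary classifies as "low").
#' @param abundance_threshold median-clr threshold (default 0; exactly at
#'   the threshold classifies as "low").
#' @return data.frame with `feature_id`, `fraction_present`,
#'   `prevalence_class`, `median_clr`, `abundance_class` and one logical
#'   `in_<label>` column per community label.
#' @export
categorize_features <- function(clr, table, communities, focal,
                                prevalence_boundary = 0.25,
                                abundance_threshold = 0) {
  table <- as_feature_table(table)
  if (is.null(names(communities))) stop("'communities' must be named by sample")
  communities <- communities[colnames(table)]
  if (anyNA(communities)) stop("community label missing for some samples")
  labels <- sort(unique(as.character(communities)))
  if (!focal %in% labels) stop("unknown focal label '", focal, "'")

  focal_samples <- colnames(table)[communities == focal]
  focal_tab <- table[, focal_samples, drop = FALSE]
  feats <- rownames(table)[rowSums(focal_tab) > 0]
  frac <- rowSums(focal_tab[feats, , drop = FALSE] > 0) / length(focal_samples)
  med <- vapply(feats, function(f) {
    median_clr(clr, features = f, samples = intersect(focal_samples,
                                                      clr$sample_ids))
  }, numeric(1))

  out <- data.frame(
    feature_id = feats,
    fraction_present = as.numeric(frac),
    prevalence_class = ifelse(frac > prevalence_boundary, "high", "low"),
    median_clr = as.numeric(med),
    abundance_class = ifelse(med > abundance_threshold, "high", "low"),
    stringsAsFactors = FALSE
  )
  for (lab in labels) {
    sub <- table[feats, communities == lab, drop = FALSE]
    out[[paste0("in_", lab)]] <- rowSums(sub) > 0
  }
  rownames(out) <- NULL
  out
}

#' Stable features between an initial and a final community
#'
#' Features present (count > 0 in >= 1 sample) in the initial-timepoint
#' table whose median clr in the final community exceeds `threshold`.
#'
#' @param initial feature table of the initial (t0) community.
#' @param final_clr `clr_distribution` of the final community.
#' @param threshold median-clr cutoff (default 0: "higher than average
#'   abundance").
#' @return character vector of stable feature ids.
#' @export
stable_features <- function(initial, final_clr, threshold = 0) {
  initial <- as_feature_table(initial)
  present_t0 <- rownames(initial)[rowSums(initial) > 0]
  shared <- intersect(present_t0, final_clr$feature_ids)
  if (!length(shared)) return(character())
  med <- vapply(shared, function(f) median_clr(final_clr, features = f),
                numeric(1))
  sort(shared[med > threshold])
}

#' Membership sets (Venn regions) across 2-3 communities
#'
#' Presence sets per label (count > 0 in >= 1 sample) partitioned into
#' all exclusive and shared Venn regions.
#'
#' @param tables named list of 2 or 3 feature tables.
#' @return object of class `membership_sets`: list with `regions`
#'   (named list of feature id vectors; names like `"A"`, `"A&B"`),
#'   `counts`, and `union_size`.
#' @export
membership_sets <- function(tables) {
  if (length(tables) < 2L || length(tables) > 3L) {
    stop("membership sets support 2 or 3 communities")
  }
  if (is.null(names(tables)) || anyDuplicated(names(tables))) {
    stop("tables must have unique names")
  }
  pres <- lapply(tables, function(t) {
    t <- as_feature_table(t)
    rownames(t)[rowSums(t) > 0]
  })
  labs <- names(pres)
  all_feats <- sort(unique(unlist(pres, use.names = FALSE)))
  membership <- vapply(pres, function(s) all_feats %in% s,
                       logical(length(all_feats)))
  if (!is.matrix(membership)) membership <- matrix(membership, nrow = 1L)
  region_of <- apply(membership, 1L, function(row) {
    paste(labs[row], collapse = "&")
  })
  # enumerate every region, including empty ones
  combos <- unlist(lapply(seq_along(labs), function(k) {
    utils::combn(labs, k, paste, collapse = "&", simplify = FALSE)
  }))
  regions <- lapply(combos, function(r) all_feats[region_of == r])
  names(regions) <- combos
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 union_size = length(all_feats)),
            class = "membership_sets")
}

#' @export
print.membership_sets <- function(x, ...) {
  cat("membership_sets (", x$union_size, " features in union)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Write a membership-set summary as JSON
#' @param sets a `membership_sets` object.
#' @param path output file.
#' @export
write_membership_sets <- function(sets, path) {
  jsonlite::write_json(unclass(sets), path, auto_unbox = TRUE, digits = NA)
  write_provenance(path, "write_membership_sets", list())
  invisible(path)
}
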