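#' Construct a feature table
#'
#' A feature table is the universal currency of the package: a features x
#' samples matrix of non-negative integer counts with unique feature and
#' sample identifiers. The constructor validates the invariants and stamps
#' the class; most operations accept any matrix coercible by
#' [as_feature_table()].
#'
#' @param counts numeric matrix (features x samples) of non-negative
#'   integers with unique rownames (feature ids) and colnames (sample ids).
#' @return an object of class `feature_table` (an integer matrix).
#' @examples
#' ft <- feature_table(matrix(c(3L, 0L, 1L, 2L), 2, 2,
#'   dimnames = list(c("asv1", "asv2"), c("s1", "s2"))))
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix")
  if ((is.null(rownames(counts)) && nrow(counts) > 0L) ||
      (is.null(colnames(counts)) && ncol(counts) > 0L)) {
    stop("feature table needs feature ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (anyNA(counts)) stop("feature table contains missing counts")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("feature_table", class(matrix()))
  counts
}

#' Coerce to a feature table
#' @param x matrix-like object of counts.
#' @return a validated `feature_table`.
#' @export
as_feature_table <- function(x) {
  if (inherits(x, "feature_table")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  feature_table(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples, total %s reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  m <- unclass(x)
  print(m[seq_len(min(6L, nrow(m))), seq_len(min(6L, ncol(m))), drop = FALSE])
  invisible(x)
}

#' @export
`[.feature_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("feature_table", class(matrix()))
  out
}

#' Read a feature table from TSV or BIOM-JSON
#'
#' The TSV dialect is features-as-rows: tab separated, first column the
#' feature id, header row of sample ids, `#` comment lines ignored. BIOM
#' is the JSON (v1.0) dialect, read through the biomformat package.
#'
#' @param path input file.
#' @param format `"tsv"` or `"biom"`.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("malformed header in ", path,
                            ": need a feature-id column plus sample columns")
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- colnames(m)[!vapply(seq_len(ncol(m)),
                                 function(j) is.numeric(df[[j + 1L]]),
                                 logical(1))][1L]
      stop("non-numeric counts in sample column '", bad, "'")
    }
    rownames(m) <- ids
    feature_table(m)
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    feature_table(m)
  }
}

#' Write a feature table to TSV or BIOM-JSON
#'
#' Writers emit a provenance sidecar (`<path>.provenance.json`) recording
#' the operation and parameters.
#'
#' @param table a [feature_table()].
#' @param path output file.
#' @param format `"tsv"` or `"biom"`.
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  table <- as_feature_table(table)
  if (format == "tsv") {
    df <- data.frame(feature_id = rownames(table), unclass(table),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- biomformat::make_biom(unclass(table))
    biomformat::write_biom(b, path)
  }
  write_provenance(path, "write_feature_table",
                   list(format = format, n_features = nrow(table),
                        n_samples = ncol(table)))
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated metadata keyed by sample id (first column `sample_id` or
#' the first column whatever its name).
#'
#' @param path metadata TSV.
#' @return data.frame with a `sample_id` column.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1L] <- "sample_id"
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df
}

#' Check that every sample in a table has a metadata record
#' @param table a feature table.
#' @param metadata data.frame from [read_sample_metadata()].
#' @return invisibly TRUE; errors listing missing samples otherwise.
#' @export
check_metadata <- function(table, metadata) {
  missing <- setdiff(colnames(table), metadata$sample_id)
  if (length(missing)) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Rarefy a feature table to even depth
#'
#' Each sample with total count >= `depth` is replaced by a
#' without-replacement subsample of exactly `depth` reads (a seeded
#' multivariate-hypergeometric draw). Samples below depth are dropped and
#' reported in the `"dropped"` attribute of the result.
#'
#' @param table a feature table.
#' @param depth positive integer target depth.
#' @param seed integer seed making the draw reproducible.
#' @return rarefied `feature_table` with attribute `dropped` (character ids).
#' @export
rarefy <- function(table, depth, seed = 1L) {
  table <- as_feature_table(table)
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0) {
    stop("'depth' must be a positive integer")
  }
  depth <- as.integer(depth)
  totals <- colSums(table)
  keep <- totals >= depth
  dropped <- colnames(table)[!keep]
  kept <- table[, keep, drop = FALSE]
  out <- with_seed(seed, {
    vapply(seq_len(ncol(kept)), function(j) {
      x <- kept[, j]
      if (sum(x) == depth) return(as.integer(x))
      reads <- rep.int(seq_along(x), x)
      tabulate(sample(reads, depth, replace = FALSE), nbins = length(x))
    }, integer(nrow(kept)))
  })
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(kept))
  dimnames(out) <- dimnames(kept)
  res <- feature_table(out)
  attr(res, "dropped") <- dropped
  attr(res, "depth") <- depth
  attr(res, "seed") <- as.integer(seed)
  res
}

#' Per-feature prevalence
#'
#' Number and fraction of samples in which each feature is observed
#' (count > 0), optionally per metadata group.
#'
#' @param table a feature table.
#' @param metadata optional metadata data.frame (required when grouping).
#' @param group_by optional metadata column name.
#' @return data.frame with `feature_id`, `group`, `n_present`,
#'   `fraction_present`.
#' @export
prevalence <- function(table, metadata = NULL, group_by = NULL) {
  table <- as_feature_table(table)
  one_group <- function(tab, label) {
    n <- ncol(tab)
    np <- if (n) as.integer(rowSums(tab > 0)) else integer(nrow(tab))
    data.frame(feature_id = rownames(tab), group = label,
               n_present = np,
               fraction_present = if (n) np / n else rep(0, nrow(tab)),
               stringsAsFactors = FALSE)
  }
  if (is.null(group_by)) {
    return(one_group(table, NA_character_))
  }
  if (is.null(metadata) || !group_by %in% names(metadata)) {
    stop("'group_by' must name a metadata column")
  }
  check_metadata(table, metadata)
  groups <- metadata[[group_by]][match(colnames(table), metadata$sample_id)]
  do.call(rbind, lapply(sort(unique(groups)), function(g) {
    one_group(table[, groups == g, drop = FALSE], g)
  }))
}
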