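RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
RANK_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Parse Greengenes-style lineage strings
#'
#' Splits `k__X; p__Y; ...` strings into a 7-column character matrix
#' (kingdom..species). Whitespace around separators is ignored; missing
#' trailing ranks and empty `x__` slots become empty strings, so parsing
#' is lossless up to canonical formatting.
#'
#' @param lineages character vector of lineage strings.
#' @return character matrix, one row per lineage, columns the 7 ranks.
#' @export
parse_lineage <- function(lineages) {
  out <- matrix("", nrow = length(lineages), ncol = 7L,
                dimnames = list(NULL, RANKS))
  for (i in seq_along(lineages)) {
    parts <- trimws(strsplit(lineages[i], ";", fixed = TRUE)[[1L]])
    for (p in parts) {
      if (p == "") next
      hit <- which(startsWith(p, RANK_PREFIXES))
      if (length(hit) == 1L) {
        out[i, hit] <- trimws(substring(p, 4L))
      }
    }
  }
  out
}

#' Format rank matrix back into lineage strings
#' @param ranks 7-column character matrix as from [parse_lineage()].
#' @param depth truncate to the first `depth` ranks (default all 7).
#' @return character vector of `k__X; p__Y; ...` strings.
#' @export
format_lineage <- function(ranks, depth = 7L) {
  apply(ranks[, seq_len(depth), drop = FALSE], 1L, function(r) {
    paste(paste0(RANK_PREFIXES[seq_len(depth)], r), collapse = "; ")
  })
}

#' Read a taxonomy map
#'
#' Two-column TSV: feature id, lineage string.
#'
#' @param path taxonomy TSV.
#' @return a `taxonomy_map`: data.frame with `feature_id` plus the 7 ranks.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxonomy file needs feature id and lineage columns")
  taxonomy_map(df[[1L]], df[[2L]])
}

#' Construct a taxonomy map from feature ids and lineage strings
#' @param feature_ids character vector of feature ids.
#' @param lineages character vector of Greengenes-style lineages.
#' @return data.frame of class `taxonomy_map`.
#' @export
taxonomy_map <- function(feature_ids, lineages) {
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids in taxonomy")
  out <- data.frame(feature_id = as.character(feature_ids),
                    parse_lineage(as.character(lineages)),
                    stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Write a taxonomy map as 2-column TSV
#' @param taxonomy a `taxonomy_map`.
#' @param path output file.
#' @export
write_taxonomy <- function(taxonomy, path) {
  df <- data.frame(feature_id = taxonomy$feature_id,
                   lineage = format_lineage(as.matrix(taxonomy[, RANKS])),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(path, "write_taxonomy", list(n = nrow(df)))
  invisible(path)
}

# ranks for the table's features, with all-empty rows for features that
# have no taxonomy record (treated as unclassified downstream)
lookup_ranks <- function(table, taxonomy) {
  idx <- match(rownames(table), taxonomy$feature_id)
  m <- matrix("", nrow = nrow(table), ncol = 7L,
              dimnames = list(rownames(table), RANKS))
  hit <- !is.na(idx)
  m[hit, ] <- as.matrix(taxonomy[idx[hit], RANKS])
  m
}

#' Remove unclassified, organellar and low-frequency features
#'
#' Drops features whose lineage is entirely unassigned (or that lack a
#' taxonomy record), whose family rank matches "mitochondria"
#' (case-insensitive), whose class or order rank matches "chloroplast"
#' (case-insensitive), or whose total count across all samples of the
#' table is <= 1 read. Everything else is retained unchanged; organellar
#' and unclassified removal is applied before the frequency rule.
#'
#' @param table a feature table.
#' @param taxonomy a `taxonomy_map`.
#' @return filtered `feature_table` (possibly empty).
#' @export
filter_features <- function(table, taxonomy) {
  table <- as_feature_table(table)
  if (nrow(table) == 0L) return(table)
  ranks <- lookup_ranks(table, taxonomy)
  unclassified <- apply(ranks, 1L, function(r) all(r == ""))
  mito <- grepl("mitochondria", ranks[, "family"], ignore.case = TRUE)
  chloro <- grepl("chloroplast", ranks[, "class"], ignore.case = TRUE) |
    grepl("chloroplast", ranks[, "order"], ignore.case = TRUE)
  keep <- !(unclassified | mito | chloro)
  out <- table[keep, , drop = FALSE]
  out[rowSums(out) > 1L, , drop = FALSE]
}

#' Collapse a feature table at a taxonomic rank
#'
#' Output features are distinct lineage prefixes truncated at `level`;
#' counts are element-wise sums over member features. Features unassigned
#' at `level` collapse under their longest assigned prefix (the truncated
#' lineage with empty slots), which keeps them distinct from assigned
#' groups. Per-sample totals are conserved exactly.
#'
#' @param table a feature table.
#' @param taxonomy a `taxonomy_map`.
#' @param level one of kingdom, phylum, class, order, family, genus, species.
#' @return collapsed `feature_table` whose feature ids are lineage prefixes.
#' @export
collapse_taxonomy <- function(table, taxonomy, level) {
  table <- as_feature_table(table)
  if (!level %in% RANKS) {
    stop("unknown rank '", level, "'; must be one of ",
         paste(RANKS, collapse = ", "))
  }
  depth <- match(level, RANKS)
  if (nrow(table) == 0L) return(table)
  ranks <- lookup_ranks(table, taxonomy)
  labels <- format_lineage(ranks, depth = depth)
  groups <- factor(labels, levels = unique(labels))
  out <- rowsum(unclass(table), groups, reorder = FALSE)
  storage.mode(out) <- "integer"
  feature_table(out)
}
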