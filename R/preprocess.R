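#' Rarefy all samples to the minimum positive depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to the smallest positive column total, so sequencing
#' effort is equal across samples. All-zero samples (annihilated microcosms)
#' bypass rarefaction and are retained as all-zero columns, because the
#' annihilation analysis needs them.
#'
#' @param table Feature table (taxa x samples).
#' @param seed Optional integer seed for reproducible subsampling.
#' @param depth Target depth; defaults to the minimum positive column total.
#' @return Feature table with every positive column summing to `depth`.
#' @export
rarefy_to_min <- function(table, seed = NULL, depth = NULL) {
  validate_feature_table(table)
  totals <- colSums(table)
  if (all(totals == 0)) stop("all samples have zero total count",
                             call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(depth)) depth <- min(totals[totals > 0])
  if (any(totals > 0 & totals < depth))
    stop("some positive samples are shallower than the target depth",
         call. = FALSE)
  out <- table
  for (j in which(totals > 0)) {
    if (totals[j] == depth) next
    reads <- rep.int(seq_len(nrow(table)), table[, j])
    keep <- sample(reads, depth)
    out[, j] <- tabulate(keep, nbins = nrow(table))
  }
  storage.mode(out) <- "integer"
  out
}

#' Filter rare taxa by grand-total fraction
#'
#' Drops every taxon whose total count across all samples is strictly less
#' than `threshold_fraction` of the table's grand total (default 1e-5, i.e.
#' 0.001%). Taxa exactly at the threshold are retained.
#'
#' @param table Feature table (taxa x samples).
#' @param threshold_fraction Fraction of the grand total below which a taxon
#'   is discarded.
#' @return List with `table` (filtered) and `dropped` (data.frame of removed
#'   taxa with their total counts and fractions).
#' @export
filter_rare <- function(table, threshold_fraction = 1e-5) {
  validate_feature_table(table)
  grand <- sum(table)
  tot <- rowSums(table)
  drop <- grand > 0 & tot < threshold_fraction * grand
  list(table = table[!drop, , drop = FALSE],
       dropped = data.frame(taxon_id = rownames(table)[drop],
                            total = tot[drop],
                            fraction = if (grand > 0) tot[drop] / grand
                                       else numeric(0),
                            row.names = NULL,
                            stringsAsFactors = FALSE))
}

#' Stack the bacterial and fungal feature tables
#'
#' Both markers are sequenced separately but analysed jointly: richness and
#' diversity downstream count bacterial and fungal ASVs together. Requires
#' identical sample sets and disjoint taxon ids.
#'
#' @param bact,fungi Feature tables (taxa x samples) over the same samples.
#' @return Combined feature table.
#' @export
merge_kingdoms <- function(bact, fungi) {
  validate_feature_table(bact)
  if (nrow(fungi) == 0) return(bact)
  validate_feature_table(fungi)
  only_b <- setdiff(colnames(bact), colnames(fungi))
  only_f <- setdiff(colnames(fungi), colnames(bact))
  if (length(only_b) || length(only_f))
    stop("sample sets differ;",
         if (length(only_b)) paste0(" only bacterial: ",
                                    paste(only_b, collapse = ", ")),
         if (length(only_f)) paste0(" only fungal: ",
                                    paste(only_f, collapse = ", ")),
         call. = FALSE)
  dup <- intersect(rownames(bact), rownames(fungi))
  if (length(dup))
    stop("taxon ids occur in both tables: ", paste(dup, collapse = ", "),
         call. = FALSE)
  rbind(bact, fungi[, colnames(bact), drop = FALSE])
}

#' Standard preprocessing: rarefy per kingdom, merge, rare-filter
#'
#' The two markers are depth-normalised separately (they were sequenced
#' separately), merged, then the rare-taxon filter is applied on the merged
#' grand total. Set `filter_per_kingdom = TRUE` to filter each kingdom
#' against its own grand total before merging instead.
#'
#' @param tables Named list of feature tables (one per kingdom), or a single
#'   feature table.
#' @param threshold_fraction Rare-taxon threshold (see [filter_rare()]).
#' @param seed Seed for rarefaction.
#' @param filter_per_kingdom Apply the rare filter within kingdom.
#' @return List with `table` and `dropped` as in [filter_rare()].
#' @export
preprocess_tables <- function(tables, threshold_fraction = 1e-5, seed = NULL,
                              filter_per_kingdom = FALSE) {
  if (is.matrix(tables)) tables <- list(tables)
  tables <- lapply(tables, rarefy_to_min, seed = seed)
  if (filter_per_kingdom) {
    filt <- lapply(tables, filter_rare, threshold_fraction = threshold_fraction)
    merged <- Reduce(merge_kingdoms, lapply(filt, `[[`, "table"))
    list(table = merged,
         dropped = do.call(rbind, lapply(filt, `[[`, "dropped")))
  } else {
    merged <- Reduce(merge_kingdoms, tables)
    filter_rare(merged, threshold_fraction = threshold_fraction)
  }
}
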