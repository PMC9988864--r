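#' Validate a feature table
#'
#' A feature table is an integer count matrix with unique taxon ids as row
#' names and unique sample ids as column names (taxa x samples).
#'
#' @param x Matrix to validate.
#' @return The matrix, invisibly, after validation.
#' @export
validate_feature_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("feature table must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("feature table needs taxon row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "feature table cells must be non-negative integers; first offender: taxon '%s', sample '%s'",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]), call. = FALSE)
  invisible(x)
}

#' Read a feature table from TSV
#'
#' @param path TSV file with a header row; the first column holds ids.
#' @param orientation `"taxa"` when rows are taxa (the canonical layout) or
#'   `"samples"` when rows are samples; the result is always taxa x samples.
#' @return Validated integer matrix, taxa x samples.
#' @export
read_feature_table <- function(path, orientation = c("taxa", "samples")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs an id column plus data columns",
                         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (orientation == "samples") m <- t(m)
  validate_feature_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a feature table to TSV (taxa as rows)
#'
#' @param table Feature table matrix.
#' @param path Output path.
#' @param id_column Name of the first (taxon id) column.
#' @export
write_feature_table <- function(table, path, id_column = "taxon_id") {
  validate_feature_table(table)
  df <- data.frame(rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `volume_ml`, `day`, `replicate`; `pH` is
#' optional (analyses needing pH skip samples with missing values). Day 0
#' marks the species-pool reference sample, for which `volume_ml` and
#' `replicate` may be missing; all other samples need a positive volume.
#'
#' @param path TSV file.
#' @return Validated data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a sample metadata table
#'
#' @param df data.frame to validate (see [read_metadata()] for the contract).
#' @return The validated data.frame (with `pH` added as NA if absent).
#' @export
validate_metadata <- function(df) {
  need <- c("sample_id", "volume_ml", "day", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"pH" %in% names(df)) df$pH <- NA_real_
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  if (anyNA(df$day) || any(df$day < 0) || any(df$day != round(df$day)))
    stop("`day` must be non-negative integers", call. = FALSE)
  if (sum(df$day == 0) > 1)
    stop("at most one sample (the pool reference) may have day 0",
         call. = FALSE)
  study <- df$day > 0
  if (anyNA(df$volume_ml[study]) || any(df$volume_ml[study] <= 0))
    stop("`volume_ml` must be positive for all study samples", call. = FALSE)
  if (anyNA(df$replicate[study]) || any(df$replicate[study] < 1))
    stop("`replicate` must be a positive integer for all study samples",
         call. = FALSE)
  df
}

#' Write sample metadata to TSV
#' @param metadata Metadata data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(validate_metadata(metadata), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Join a feature table with sample metadata
#'
#' Fails loudly when the sample sets differ, listing every unmatched id on
#' both sides. On success the metadata rows are reordered to the table's
#' column order.
#'
#' @param table Feature table (taxa x samples).
#' @param metadata Metadata data.frame.
#' @return List of class `mc_dataset` with elements `features` and
#'   `metadata`, columns and rows aligned.
#' @export
join_dataset <- function(table, metadata) {
  validate_feature_table(table)
  metadata <- validate_metadata(metadata)
  only_tab <- setdiff(colnames(table), metadata$sample_id)
  only_meta <- setdiff(metadata$sample_id, colnames(table))
  if (length(only_tab) || length(only_meta))
    stop("sample sets differ between table and metadata;",
         if (length(only_tab)) paste0(" only in table: ",
                                      paste(only_tab, collapse = ", ")),
         if (length(only_meta)) paste0(" only in metadata: ",
                                       paste(only_meta, collapse = ", ")),
         call. = FALSE)
  metadata <- metadata[match(colnames(table), metadata$sample_id), ]
  rownames(metadata) <- NULL
  structure(list(features = table, metadata = metadata),
            class = "mc_dataset")
}

#' Read a taxon trait map from TSV
#'
#' Columns: `taxon_id`, `kingdom` (`bacteria`/`fungi`), `acid_flag`
#' (`TRUE`/`FALSE`/`unknown`).
#'
#' @param path TSV file.
#' @return data.frame with `acid_flag` as logical (NA = unknown).
#' @export
read_traits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "kingdom", "acid_flag")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trait map is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon ids in trait map", call. = FALSE)
  if (!all(df$kingdom %in% c("bacteria", "fungi")))
    stop("`kingdom` must be 'bacteria' or 'fungi'", call. = FALSE)
  flag <- tolower(as.character(df$acid_flag))
  df$acid_flag <- ifelse(flag %in% c("true", "t", "1"), TRUE,
                         ifelse(flag %in% c("false", "f", "0"), FALSE, NA))
  df
}

#' Write a simulation to disk as tidy TSVs
#'
#' Writes `features.tsv`, `metadata.tsv`, `pool.tsv` and `truth.tsv`
#' (taxon-level latent death days per flask) into a directory.
#'
#' @param sim An `mc_sim` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mc_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(sim$features, file.path(dir, "features.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  utils::write.table(sim$pool, file.path(dir, "pool.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fl <- sim$truth$flasks
  truth <- data.frame(
    flask = rep(sprintf("V%g_R%d", fl$volume_ml, fl$replicate),
                each = nrow(sim$pool)),
    volume_ml = rep(fl$volume_ml, each = nrow(sim$pool)),
    replicate = rep(fl$replicate, each = nrow(sim$pool)),
    taxon_id = rep(sim$pool$taxon_id, nrow(fl)),
    death_day = as.vector(sim$truth$death_day),
    stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a feature table as BIOM-format JSON
#'
#' Interoperability writer using the `biomformat` package (BIOM 1.0 JSON).
#'
#' @param table Feature table (taxa x samples).
#' @param path Output path.
#' @export
write_biom_json <- function(table, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the `biomformat` package is required for BIOM output",
         call. = FALSE)
  validate_feature_table(table)
  biomformat::write_biom(biomformat::make_biom(table), path)
}

#' Read a feature table from BIOM-format JSON
#'
#' @param path BIOM 1.0 JSON file.
#' @return Validated integer matrix, taxa x samples.
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the `biomformat` package is required for BIOM input", call. = FALSE)
  m <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
  storage.mode(m) <- "double"
  validate_feature_table(m)
  storage.mode(m) <- "integer"
  m
}
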