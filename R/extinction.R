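#' Species-pool taxon set of a dataset
#'
#' The pool is the set of taxa observed in the day-0 reference sample of the
#' shared starting material. Extinction is always scored against this set.
#'
#' @param dataset An `mc_dataset` (see [join_dataset()]).
#' @return Character vector of pool taxon ids.
#' @export
pool_taxa <- function(dataset) {
  meta <- dataset$metadata
  idx <- which(meta$day == 0)
  if (length(idx) != 1)
    stop("dataset must contain exactly one day-0 pool reference sample",
         call. = FALSE)
  rownames(dataset$features)[dataset$features[, meta$sample_id[idx]] > 0]
}

#' Extinction rate of one sample
#'
#' The number of pool taxa undetected (count 0) in the sample divided by the
#' pool size. True extinction and non-detection are indistinguishable in the
#' data; this is a measurement definition.
#'
#' @param counts Count vector named by taxon id (one sample).
#' @param pool Character vector of pool taxon ids.
#' @return List with `n_pool`, `n_lost`, `extinction_rate`.
#' @export
extinction_rate <- function(counts, pool) {
  if (length(pool) == 0) stop("species pool is empty", call. = FALSE)
  present <- names(counts)[counts > 0]
  n_lost <- length(setdiff(pool, present))
  list(n_pool = length(pool), n_lost = n_lost,
       extinction_rate = n_lost / length(pool))
}

#' Per-sample extinction records for a dataset
#'
#' @param dataset An `mc_dataset`.
#' @param pool Pool taxon ids; defaults to [pool_taxa()] of the dataset.
#' @return data.frame: `sample_id`, `day`, `volume_ml`, `replicate`,
#'   `n_pool`, `n_lost`, `extinction_rate` (pool sample excluded).
#' @export
extinction_records <- function(dataset, pool = pool_taxa(dataset)) {
  if (length(pool) == 0) stop("species pool is empty", call. = FALSE)
  meta <- dataset$metadata
  study <- meta$day > 0
  sub <- dataset$features[rownames(dataset$features) %in% pool,
                          meta$sample_id[study], drop = FALSE]
  n_detected <- colSums(sub > 0)
  data.frame(sample_id = meta$sample_id[study],
             day = meta$day[study],
             volume_ml = meta$volume_ml[study],
             replicate = meta$replicate[study],
             n_pool = length(pool),
             n_lost = length(pool) - n_detected,
             extinction_rate = (length(pool) - n_detected) / length(pool),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Is a sample an annihilated microcosm?
#'
#' A microcosm is annihilated when no microorganisms are detected at all.
#'
#' @param counts Count vector of one sample.
#' @return Logical.
#' @export
is_annihilated <- function(counts) {
  all(counts == 0)
}

#' Annihilation rate per time point
#'
#' Fraction of microcosms with no detected taxa at each sampled day.
#'
#' @param dataset An `mc_dataset`.
#' @return data.frame: `day`, `n_total`, `n_annihilated`,
#'   `annihilation_rate`.
#' @export
annihilation_rates <- function(dataset) {
  meta <- dataset$metadata
  study <- meta$day > 0
  dead <- colSums(dataset$features[, meta$sample_id[study],
                                   drop = FALSE] > 0) == 0
  days <- sort(unique(meta$day[study]))
  n_tot <- vapply(days, function(d) sum(meta$day[study] == d), integer(1))
  n_ann <- vapply(days, function(d) sum(dead[meta$day[study] == d]),
                  integer(1))
  data.frame(day = days, n_total = n_tot, n_annihilated = n_ann,
             annihilation_rate = n_ann / n_tot,
             row.names = NULL)
}

#' Pearson correlation of extinction rate with volume, per time point
#'
#' At each sampled day, Pearson r of extinction rate on flask volume with a
#' two-sided test. A day is flagged `negative` when r < 0 and p < alpha.
#' Days with fewer than 3 records, a single volume or zero variance in
#' either variable are flagged `not_assessable`.
#'
#' @param records Extinction records from [extinction_records()].
#' @param alpha Significance level.
#' @param log_volume Correlate against log10(volume) instead of raw volume.
#' @return data.frame: `day`, `n`, `r`, `p_value`, `flag`.
#' @export
correlate_extinction_volume <- function(records, alpha = 0.05,
                                        log_volume = FALSE) {
  days <- sort(unique(records$day))
  rows <- lapply(days, function(d) {
    sub <- records[records$day == d, ]
    x <- if (log_volume) log10(sub$volume_ml) else sub$volume_ml
    y <- sub$extinction_rate
    if (nrow(sub) < 3 || length(unique(x)) < 2 ||
        stats::var(y) == 0 || stats::var(x) == 0)
      return(data.frame(day = d, n = nrow(sub), r = NA_real_,
                        p_value = NA_real_, flag = "not_assessable",
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    data.frame(day = d, n = nrow(sub), r = unname(ct$estimate),
               p_value = ct$p.value,
               flag = if (ct$estimate < 0 && ct$p.value < alpha)
                 "negative" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Detect mass-extinction events
#'
#' Flags a sampled day when the mean extinction rate rises by at least
#' `delta` (absolute, on the 0-1 scale) relative to the previous sampled
#' day.
#'
#' @param day Vector of sampled days (sorted or sortable).
#' @param mean_rate Mean extinction rate per day, same length.
#' @param delta Jump threshold in absolute rate units (0.10 = 10 percentage
#'   points).
#' @return Integer vector of flagged days.
#' @export
detect_mass_extinctions <- function(day, mean_rate, delta = 0.10) {
  if (length(day) != length(mean_rate))
    stop("`day` and `mean_rate` lengths differ", call. = FALSE)
  o <- order(day)
  day <- day[o]; mean_rate <- mean_rate[o]
  if (length(day) < 2) return(integer(0))
  jumps <- diff(mean_rate)
  as.integer(day[-1][jumps >= delta & !is.na(jumps)])
}

#' Mean daily extinction rate series of a dataset
#'
#' Convenience wrapper: per-day mean of the per-sample extinction rates.
#'
#' @param records Extinction records from [extinction_records()].
#' @return data.frame: `day`, `mean_rate`, `sd_rate`, `n`.
#' @export
mean_extinction_series <- function(records) {
  days <- sort(unique(records$day))
  data.frame(
    day = days,
    mean_rate = vapply(days, function(d)
      mean(records$extinction_rate[records$day == d]), numeric(1)),
    sd_rate = vapply(days, function(d)
      stats::sd(records$extinction_rate[records$day == d]), numeric(1)),
    n = vapply(days, function(d) sum(records$day == d), integer(1)))
}

#' Mean extinction rate per successional phase
#'
#' Mean and sample (n-1) standard deviation of the per-sample extinction
#' rates within each phase of a segmentation. Phases containing no sampled
#' records are omitted with a warning.
#'
#' @param records Extinction records from [extinction_records()].
#' @param segmentation A `phase_segmentation` (see [segment_phases()]) or a
#'   data.frame with columns `label`, `start`, `end`.
#' @return data.frame: `phase`, `start`, `end`, `n`, `mean`, `sd`.
#' @export
phase_mean_extinction <- function(records, segmentation) {
  ph <- as.data.frame(segmentation)
  rows <- lapply(seq_len(nrow(ph)), function(i) {
    sel <- records$day >= ph$start[i] & records$day <= ph$end[i]
    if (!any(sel)) {
      warning("phase '", ph$label[i], "' contains no sampled records; omitted",
              call. = FALSE)
      return(NULL)
    }
    data.frame(phase = ph$label[i], start = ph$start[i], end = ph$end[i],
               n = sum(sel),
               mean = mean(records$extinction_rate[sel]),
               sd = stats::sd(records$extinction_rate[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
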