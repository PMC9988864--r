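#' Per-sample species richness
#'
#' Richness is the number of taxa observed (count > 0), bacterial and fungal
#' ASVs counted together.
#'
#' @param table Feature table (taxa x samples).
#' @return Named integer vector, one entry per sample.
#' @export
richness <- function(table) {
  validate_feature_table(table)
  r <- colSums(table > 0)
  stats::setNames(as.integer(r), names(r))
}

#' Fit the semi-logarithmic species-area relationship at one time point
#'
#' Ordinary least squares of richness S on log(volume): S = c + b * log(A),
#' with a two-sided t-test on the slope. Classification: `positive` when
#' p < alpha and b > 0; `negative` when p < alpha and b < 0; `none`
#' otherwise. The classification is invariant to the log base; slope and
#' intercept are reported in `log_base` (default 10).
#'
#' @param volume Vector of flask volumes (mL).
#' @param richness Matching vector of species richness values.
#' @param alpha Significance level for the slope test.
#' @param log_base Base of the logarithm applied to volume.
#' @param day Optional day label carried into the result.
#' @return Object of class `sar_fit`: list with `day`, `n_points`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `classification`, and `ci_band`
#'   (per-volume fitted value with 95% confidence limits).
#' @export
fit_sar <- function(volume, richness, alpha = 0.05, log_base = 10,
                    day = NA_integer_) {
  if (length(volume) != length(richness))
    stop("`volume` and `richness` lengths differ", call. = FALSE)
  keep <- !is.na(volume) & !is.na(richness)
  volume <- volume[keep]; richness <- richness[keep]
  if (length(volume) < 3 || length(unique(volume)) < 2)
    stop("insufficient data: need >= 3 points spanning >= 2 volumes",
         call. = FALSE)
  x <- log(volume, base = log_base)
  fit <- stats::lm(richness ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  slope <- unname(stats::coef(fit)[2])
  if (nrow(sm$coefficients) < 2 || !is.finite(sm$coefficients[2, 4])) {
    p <- 1; slope_se <- NA_real_
  } else {
    p <- sm$coefficients[2, 4]
    slope_se <- sm$coefficients[2, 2]
  }
  cls <- if (p < alpha && slope > 0) "positive"
         else if (p < alpha && slope < 0) "negative" else "none"
  vgrid <- sort(unique(volume))
  band <- stats::predict(fit, newdata = data.frame(x = log(vgrid, log_base)),
                         interval = "confidence", level = 0.95)
  structure(list(day = day,
                 n_points = length(volume),
                 slope = slope,
                 slope_se = slope_se,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p,
                 classification = cls,
                 alpha = alpha,
                 log_base = log_base,
                 ci_band = data.frame(volume_ml = vgrid,
                                      fit = band[, "fit"],
                                      lwr = band[, "lwr"],
                                      upr = band[, "upr"])),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf(
    "SAR fit%s: S = %.3f %+.3f log%g(A); R2 = %.3f, p = %.3g -> %s (n = %d)\n",
    if (is.na(x$day)) "" else sprintf(" (day %d)", x$day),
    x$intercept, x$slope, x$log_base, x$r_squared, x$p_value,
    x$classification, x$n_points))
  invisible(x)
}

#' Scan the semi-log SAR across all sampled time points
#'
#' Fits [fit_sar()] once per schedule day using all replicate flasks sampled
#' that day. Annihilated flasks enter with richness 0 by default (they are
#' real observations of the community); set `drop_annihilated = TRUE` to
#' exclude them. Days with insufficient data (fewer than 3 usable points, a
#' single volume, or all-zero richness with no variance) are reported as
#' `not_assessable` rather than aborting the scan.
#'
#' @param dataset An `mc_dataset` from [join_dataset()] (or a list with
#'   `features` and `metadata`).
#' @param alpha Significance level.
#' @param log_base Log base for volume.
#' @param drop_annihilated Exclude all-zero samples from the fits.
#' @param aggregate Average richness over replicates within a volume before
#'   fitting (7 points per day instead of 21).
#' @param adjust_p Optional p-value adjustment across days (`"none"` or
#'   `"BH"`).
#' @return data.frame of class `sar_scan`, one row per day: `day`, `n`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `classification`. The
#'   full `sar_fit` objects are attached as attribute `fits`.
#' @export
sar_scan <- function(dataset, alpha = 0.05, log_base = 10,
                     drop_annihilated = FALSE, aggregate = FALSE,
                     adjust_p = c("none", "BH")) {
  adjust_p <- match.arg(adjust_p)
  feats <- dataset$features
  meta <- dataset$metadata
  study <- meta$day > 0
  rich <- richness(feats)
  days <- sort(unique(meta$day[study]))
  fits <- vector("list", length(days))
  rows <- vector("list", length(days))
  for (i in seq_along(days)) {
    sel <- study & meta$day == days[i]
    v <- meta$volume_ml[sel]
    s <- unname(rich[meta$sample_id[sel]])
    if (drop_annihilated) {
      keep <- s > 0
      v <- v[keep]; s <- s[keep]
    }
    if (aggregate && length(v)) {
      agg <- tapply(s, v, mean)
      v <- as.numeric(names(agg)); s <- unname(agg)
    }
    f <- tryCatch(fit_sar(v, s, alpha = alpha, log_base = log_base,
                          day = days[i]),
                  error = function(e) NULL)
    if (is.null(f) || (stats::var(s) == 0)) {
      rows[[i]] <- data.frame(day = days[i], n = length(v),
                              slope = NA_real_, intercept = NA_real_,
                              r_squared = NA_real_, p_value = NA_real_,
                              classification = "not_assessable",
                              stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- f
      rows[[i]] <- data.frame(day = days[i], n = f$n_points,
                              slope = f$slope, intercept = f$intercept,
                              r_squared = f$r_squared, p_value = f$p_value,
                              classification = f$classification,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust_p == "BH") {
    padj <- stats::p.adjust(out$p_value, method = "BH")
    assessable <- out$classification != "not_assessable"
    out$p_adjusted <- padj
    out$classification[assessable] <-
      ifelse(padj[assessable] < alpha & out$slope[assessable] > 0, "positive",
      ifelse(padj[assessable] < alpha & out$slope[assessable] < 0, "negative",
             "none"))
  }
  attr(out, "fits") <- fits
  class(out) <- c("sar_scan", "data.frame")
  out
}

#' Summarise temporal occurrence of the positive SAR
#'
#' Two fractions: (a) the share of assessed time points classified positive;
#' (b) the share of the observation period covered by positive SARs, where a
#' maximal run of consecutive positive schedule days from day d1 to d2
#' contributes d2 - d1 + 1 calendar days (an isolated positive day
#' contributes 1), divided by `total_days`. "Consecutive" means adjacent
#' positions in the sampling schedule. Negative SARs are listed but never
#' counted in the positive fractions.
#'
#' @param fits A `sar_scan` data.frame, or a data.frame with columns `day`
#'   and `classification`.
#' @param design The [mc_design()] supplying the schedule and `total_days`.
#' @return List of class `sar_occurrence`: `timepoint_fraction`,
#'   `period_fraction`, `period_days`, `positive_days`, `negative_days`,
#'   `n_timepoints`.
#' @export
summarize_occurrence <- function(fits, design) {
  stopifnot(inherits(design, "mc_design"))
  sched <- design$schedule_days
  cls <- fits$classification[match(sched, fits$day)]
  cls[is.na(cls)] <- "not_assessable"
  pos <- sched[cls == "positive"]
  neg <- sched[cls == "negative"]
  covered <- 0L
  if (length(pos)) {
    idx <- match(pos, sched)
    run_id <- cumsum(c(1L, diff(idx) != 1L))
    covered <- sum(tapply(pos, run_id, function(d) max(d) - min(d) + 1L))
  }
  structure(list(
    timepoint_fraction = length(pos) / length(sched),
    period_fraction = covered / design$total_days,
    period_days = as.integer(covered),
    positive_days = pos,
    negative_days = neg,
    n_timepoints = length(sched)), class = "sar_occurrence")
}

#' @export
print.sar_occurrence <- function(x, ...) {
  cat(sprintf(
    "Positive SAR at %d/%d time points (%.2f%%), covering %d days (%.2f%% of the period)\n",
    length(x$positive_days), x$n_timepoints, 100 * x$timepoint_fraction,
    x$period_days, 100 * x$period_fraction))
  if (length(x$positive_days))
    cat("  positive days:", paste(x$positive_days, collapse = ", "), "\n")
  if (length(x$negative_days))
    cat("  negative days:", paste(x$negative_days, collapse = ", "), "\n")
  invisible(x)
}
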