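#' Microcosm study design
#'
#' A `mc_design` records the volumetric gradient, replication and sampling
#' schedule of a closed-microcosm monitoring study. Flasks are sampled
#' destructively, so the number of flasks prepared per volume class equals
#' `n_replicates * length(schedule_days)`.
#'
#' @param volumes_ml Strictly increasing vector of flask volumes in mL.
#' @param n_replicates Number of independent microcosms sampled per volume
#'   and time point.
#' @param schedule_days Strictly increasing vector of sampling days
#'   (1-based; day 0 is reserved for the species-pool reference sample and
#'   never appears here).
#' @param total_days Length of the observation period in days; must be at
#'   least `max(schedule_days)`.
#' @return An object of class `mc_design`.
#' @examples
#' d <- mc_design()          # the default 7-volume, 3-replicate, 26-day design
#' flasks_per_volume(d)      # 78
#' nrow(enumerate_samples(d))# 546
#' @export
mc_design <- function(volumes_ml = c(10, 20, 50, 100, 250, 500, 1000),
                      n_replicates = 3L,
                      schedule_days = build_schedule(10, 30, 60),
                      total_days = 60L) {
  if (!is.numeric(volumes_ml) || length(volumes_ml) < 1 || anyNA(volumes_ml))
    stop("`volumes_ml` must be a non-empty numeric vector", call. = FALSE)
  if (any(volumes_ml <= 0) || is.unsorted(volumes_ml, strictly = TRUE))
    stop("`volumes_ml` must be strictly increasing and positive", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  if (length(n_replicates) != 1 || is.na(n_replicates) || n_replicates < 1)
    stop("`n_replicates` must be a single positive integer", call. = FALSE)
  schedule_days <- as.integer(schedule_days)
  if (length(schedule_days) < 1 || anyNA(schedule_days) ||
      any(schedule_days < 1) || is.unsorted(schedule_days, strictly = TRUE))
    stop("`schedule_days` must be strictly increasing positive integers",
         call. = FALSE)
  total_days <- as.integer(total_days)
  if (length(total_days) != 1 || is.na(total_days) ||
      total_days < max(schedule_days))
    stop("`total_days` must be >= max(schedule_days)", call. = FALSE)
  structure(
    list(volumes_ml = as.numeric(volumes_ml),
         n_replicates = n_replicates,
         schedule_days = schedule_days,
         total_days = total_days),
    class = "mc_design")
}

#' @export
print.mc_design <- function(x, ...) {
  cat("Microcosm study design\n")
  cat("  volumes (mL):", paste(x$volumes_ml, collapse = ", "), "\n")
  cat("  replicates: ", x$n_replicates, "\n")
  cat(sprintf("  schedule:    %d time points within %d days\n",
              length(x$schedule_days), x$total_days))
  cat(sprintf("  flasks:      %d per volume, %d samples total\n",
              flasks_per_volume(x), nrow(enumerate_samples(x))))
  invisible(x)
}

#' Build a three-block sampling schedule
#'
#' Sampling is daily up to `daily_until`, every 2 days up to `step2_until`,
#' then every 5 days up to `step5_until`. A block boundary day belongs to the
#' earlier block and is not repeated: the 2-day block starts at
#' `daily_until + 2` and the 5-day block at `step2_until + 5`.
#'
#' @param daily_until Last day of the daily block.
#' @param step2_until Last day of the every-2-days block.
#' @param step5_until Last day of the every-5-days block.
#' @return Strictly increasing integer vector of sampling days.
#' @examples
#' build_schedule(10, 30, 60)  # the default 26-point schedule
#' @export
build_schedule <- function(daily_until, step2_until, step5_until) {
  b <- c(daily_until, step2_until, step5_until)
  if (length(b) != 3 || anyNA(b) || any(b != as.integer(b)))
    stop("schedule bounds must be single integers", call. = FALSE)
  if (!(0 < daily_until && daily_until < step2_until &&
        step2_until < step5_until))
    stop("schedule bounds must satisfy 0 < daily < step2 < step5",
         call. = FALSE)
  block <- function(from, to, by)
    if (from <= to) seq(from, to, by = by) else integer(0)
  as.integer(c(seq_len(daily_until),
               block(daily_until + 2L, step2_until, 2L),
               block(step2_until + 5L, step5_until, 5L)))
}

#' Enumerate all (volume, replicate, day) sampling units of a design
#'
#' @param design An [mc_design()].
#' @return A data.frame with columns `volume_ml`, `replicate`, `day`, one row
#'   per destructively sampled flask.
#' @export
enumerate_samples <- function(design) {
  stopifnot(inherits(design, "mc_design"))
  out <- expand.grid(replicate = seq_len(design$n_replicates),
                     volume_ml = design$volumes_ml,
                     day = design$schedule_days,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[c("volume_ml", "replicate", "day")]
  rownames(out) <- NULL
  out
}

#' Number of flasks prepared per volume class
#'
#' Destructive sampling: each (replicate, day) combination consumes one flask.
#'
#' @param design An [mc_design()].
#' @return Integer.
#' @export
flasks_per_volume <- function(design) {
  stopifnot(inherits(design, "mc_design"))
  design$n_replicates * length(design$schedule_days)
}
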