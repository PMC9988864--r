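#' Bell-form (Gaussian-plus-offset) nonlinear regression
#'
#' Least-squares fit of y(t) = d + a * exp(-(t - mu)^2 / (2 * sigma^2)) with
#' free-sign amplitude, used for pH (negative amplitude: a dip) and
#' annihilation-rate trajectories. Initialisation is a deterministic
#' multi-start grid (mu at the quartiles of the day range, sigma at range/8
#' and range/4, amplitude and offset from the data extremes); the start with
#' the best optimised SSE wins, ties broken by grid order. R-squared is
#' measured against the constant-mean model and the p-value is an F-test of
#' the 4-parameter model against the constant model with (3, n - 4) degrees
#' of freedom.
#'
#' @param day Numeric vector of days (>= 5 points required).
#' @param value Matching response vector.
#' @return Object of class `bell_fit`: `a`, `mu`, `sigma`, `d`, `r_squared`,
#'   `p_value`, `converged`, `fitted`, `sse`. On total failure `converged` is
#'   FALSE and the parameters are NA (no exception is thrown).
#' @export
fit_bell <- function(day, value) {
  keep <- is.finite(day) & is.finite(value)
  day <- day[keep]; value <- value[keep]
  n <- length(day)
  if (n < 5) stop("bell fit needs at least 5 points", call. = FALSE)
  rng <- range(day)
  span <- max(rng[2] - rng[1], 1)
  sse_fun <- function(p) {
    mu <- p[1]; lsig <- p[2]; a <- p[3]; d <- p[4]
    r <- value - (d + a * exp(-(day - mu)^2 / (2 * exp(2 * lsig))))
    sum(r * r)
  }
  mu0 <- stats::quantile(day, c(0.25, 0.5, 0.75), names = FALSE)
  sig0 <- c(span / 8, span / 4)
  a0 <- c(min(value) - stats::median(value),
          max(value) - stats::median(value))
  d0 <- c(min(value), stats::median(value), max(value))
  best <- NULL
  for (mu in mu0) for (s in sig0) for (a in a0) for (d in d0) {
    fit <- tryCatch(
      stats::optim(c(mu, log(s), a, d), sse_fun, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value - 1e-12))
      best <- fit
  }
  if (is.null(best)) {
    return(structure(list(a = NA_real_, mu = NA_real_, sigma = NA_real_,
                          d = NA_real_, r_squared = NA_real_,
                          p_value = NA_real_, converged = FALSE,
                          fitted = rep(NA_real_, n), sse = NA_real_,
                          day = day, value = value),
                     class = "bell_fit"))
  }
  # polish the best grid solution to high precision (Gauss-Newton)
  polish <- suppressWarnings(tryCatch({
    st <- list(mu = best$par[1], lsig = best$par[2],
               a = best$par[3], d = best$par[4])
    nf <- stats::nls(value ~ d + a * exp(-(day - mu)^2 / (2 * exp(2 * lsig))),
                     start = st,
                     control = stats::nls.control(maxiter = 200,
                                                  tol = 1e-12,
                                                  minFactor = 1e-12,
                                                  scaleOffset = 1,
                                                  warnOnly = TRUE))
    cf <- stats::coef(nf)
    list(par = c(cf[["mu"]], cf[["lsig"]], cf[["a"]], cf[["d"]]))
  }, error = function(e) NULL))
  if (!is.null(polish) && sse_fun(polish$par) <= best$value)
    best$par <- polish$par
  best$value <- sse_fun(best$par)
  p <- best$par
  fitted <- p[4] + p[3] * exp(-(day - p[1])^2 / (2 * exp(2 * p[2])))
  sse <- best$value
  sst <- sum((value - mean(value))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  pval <- if (sst > sse && n > 4 && sse > 0) {
    f <- ((sst - sse) / 3) / (sse / (n - 4))
    stats::pf(f, 3, n - 4, lower.tail = FALSE)
  } else if (sse == 0 && sst > 0) 0 else 1
  structure(list(a = p[3], mu = p[1], sigma = exp(p[2]), d = p[4],
                 r_squared = r2, p_value = pval, converged = TRUE,
                 fitted = fitted, sse = sse, day = day, value = value),
            class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  if (!x$converged) { cat("Bell fit: did not converge\n"); return(invisible(x)) }
  cat(sprintf(
    "Bell fit: y = %.4g %+.4g exp(-(t - %.4g)^2 / (2 * %.4g^2)); R2 = %.3f, p = %.3g\n",
    x$d, x$a, x$mu, x$sigma, x$r_squared, x$p_value))
  invisible(x)
}

#' Segment the observation period into successional phases
#'
#' Three phases are delimited from the mean pH series: Phase 1 (rapid pH
#' decline) ends at the last day before the per-day pH change magnitude
#' first falls below a threshold; Phase 3 (recovery) starts at the end of
#' the first interval over which pH rises faster than the threshold,
#' sustained for at least `min_sustained` consecutive intervals. The
#' threshold is `slope_frac` times the maximum observed per-day |change|.
#' With fewer than three detectable regimes a best-effort segmentation is
#' returned with a warning. Explicit ranges can be forced via `phases`.
#'
#' @param day Sorted vector of sampled days.
#' @param ph Mean pH per day (same length).
#' @param slope_frac Threshold as a fraction of the maximum per-day |dpH/dt|.
#' @param min_sustained Number of consecutive rising intervals required to
#'   call the recovery onset.
#' @param phases Optional manual override: data.frame with `label`, `start`,
#'   `end` covering all sampled days.
#' @return data.frame of class `phase_segmentation` with columns `label`,
#'   `start`, `end`.
#' @export
segment_phases <- function(day, ph, slope_frac = 0.25, min_sustained = 2,
                           phases = NULL) {
  if (!is.null(phases)) {
    out <- as.data.frame(phases)
    stopifnot(all(c("label", "start", "end") %in% names(out)))
    class(out) <- c("phase_segmentation", "data.frame")
    return(out)
  }
  o <- order(day)
  day <- day[o]; ph <- ph[o]
  keep <- is.finite(ph)
  day <- day[keep]; ph <- ph[keep]
  n <- length(day)
  if (n < 3) {
    warning("too few pH points; returning a single phase", call. = FALSE)
    out <- data.frame(label = "Phase 1", start = min(day), end = max(day))
    class(out) <- c("phase_segmentation", "data.frame")
    return(out)
  }
  rate <- diff(ph) / diff(day)                     # per-interval slope
  thr <- slope_frac * max(abs(rate))
  single <- function(msg) {
    warning(msg, call. = FALSE)
    out <- data.frame(label = "Phase 1", start = day[1], end = day[n])
    class(out) <- c("phase_segmentation", "data.frame")
    out
  }
  if (max(abs(rate)) == 0)
    return(single("pH series is constant; returning a single phase"))
  # end of rapid decline: first interval at/after the steepest change whose
  # |rate| drops below threshold (earlier flat intervals predate the decline)
  steepest <- which.max(abs(rate))
  flat <- which(abs(rate) < thr & seq_along(rate) >= steepest)
  if (!length(flat))
    return(single("no stable pH regime detected; returning a single phase"))
  p1_end_idx <- flat[1]                            # interval (i, i+1)
  # recovery onset: first sustained run of rising intervals after the decline
  rising <- rate > thr
  p3_start_idx <- NA_integer_
  for (i in seq(p1_end_idx, length(rate))) {
    run <- i:min(i + min_sustained - 1, length(rate))
    if (length(run) == min_sustained && all(rising[run])) {
      p3_start_idx <- i; break
    }
  }
  if (is.na(p3_start_idx)) {
    warning("no sustained pH recovery detected; returning two phases",
            call. = FALSE)
    out <- data.frame(label = c("Phase 1", "Phase 2"),
                      start = c(day[1], day[p1_end_idx + 1]),
                      end = c(day[p1_end_idx], day[n]))
    class(out) <- c("phase_segmentation", "data.frame")
    return(out)
  }
  p3_start <- day[p3_start_idx + 1]                # end of the rising interval
  p2_end <- day[p3_start_idx]
  out <- data.frame(label = c("Phase 1", "Phase 2", "Phase 3"),
                    start = c(day[1], day[p1_end_idx + 1], p3_start),
                    end = c(day[p1_end_idx], p2_end, day[n]))
  class(out) <- c("phase_segmentation", "data.frame")
  out
}

#' Shannon diversity of one sample
#'
#' H = -sum(p_i * ln(p_i)) over taxa with positive counts, natural log.
#' All-zero samples have undefined diversity and return NA.
#'
#' @param counts Count (or abundance) vector of one sample.
#' @return Numeric, or NA for an empty sample.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Per-sample Shannon diversity of a dataset
#'
#' @param dataset An `mc_dataset`.
#' @return data.frame: `sample_id`, `day`, `volume_ml`, `shannon` (NA for
#'   annihilated samples; pool sample excluded).
#' @export
shannon_table <- function(dataset) {
  meta <- dataset$metadata
  study <- meta$day > 0
  h <- apply(dataset$features[, meta$sample_id[study], drop = FALSE], 2,
             shannon)
  data.frame(sample_id = meta$sample_id[study], day = meta$day[study],
             volume_ml = meta$volume_ml[study], shannon = unname(h),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise Wilcoxon rank-sum tests of diversity between phases
#'
#' Two-sided rank-sum test for every phase pair. `stats::wilcox.test` uses
#' the exact null for small samples without ties and the tie-corrected
#' normal approximation otherwise. Samples with undefined diversity
#' (annihilated) are dropped.
#'
#' @param diversity data.frame with columns `day` and a value column.
#' @param segmentation A `phase_segmentation`.
#' @param value Name of the value column (default `"shannon"`).
#' @return data.frame: `group1`, `group2`, `n1`, `n2`, `p_value`.
#' @export
phase_diversity_test <- function(diversity, segmentation,
                                 value = "shannon") {
  ph <- as.data.frame(segmentation)
  groups <- lapply(seq_len(nrow(ph)), function(i) {
    v <- diversity[[value]][diversity$day >= ph$start[i] &
                            diversity$day <= ph$end[i]]
    v[is.finite(v)]
  })
  names(groups) <- ph$label
  pairs <- utils::combn(seq_along(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (length(groups[[i]]) < 2 || length(groups[[j]]) < 2) return(NULL)
    p <- suppressWarnings(
      stats::wilcox.test(groups[[i]], groups[[j]],
                         alternative = "two.sided")$p.value)
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               n1 = length(groups[[i]]), n2 = length(groups[[j]]),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(i, j) = 1 - 2 * sum(min(x_i, x_j)) / (sum(x_i) + sum(x_j)), computed
#' over all sample pairs. Samples are columns of the feature table.
#'
#' @param table Feature table (taxa x samples); all-zero samples are
#'   excluded.
#' @return A `dist` object over the retained samples.
#' @export
bray_curtis <- function(table) {
  validate_feature_table(table)
  keep <- colSums(table) > 0
  vegan::vegdist(t(table[, keep, drop = FALSE]), method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal NMDS (stress-1) via `vegan::monoMDS`, deterministic given the
#' seed. Degenerate inputs (all-zero dissimilarity) are refused with an
#' error.
#'
#' @param dissimilarity A `dist` object (e.g. from [bray_curtis()]).
#' @param k Embedding dimension.
#' @param seed RNG seed for the random starts.
#' @param trymax Number of random starts.
#' @return List of class `mc_nmds`: `points` (n x k coordinates), `stress`
#'   (final stress-1, as a fraction of 1).
#' @export
nmds_ordination <- function(dissimilarity, k = 2, seed = 1, trymax = 20) {
  stopifnot(inherits(dissimilarity, "dist"))
  if (attr(dissimilarity, "Size") < 3)
    stop("NMDS needs at least 3 samples", call. = FALSE)
  if (all(dissimilarity == 0))
    stop("all samples identical: zero dissimilarity everywhere, NMDS skipped",
         call. = FALSE)
  set.seed(as.integer(seed))
  best <- NULL
  for (i in seq_len(trymax)) {
    m <- vegan::monoMDS(dissimilarity, k = k, model = "global")
    if (is.null(best) || m$stress < best$stress) best <- m
  }
  structure(list(points = best$points, stress = best$stress),
            class = "mc_nmds")
}
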