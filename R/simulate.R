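#' Draw a species pool
#'
#' The pool is the taxon set of the shared, well-mixed starting material.
#' Relative abundances are lognormal; bacterial taxa are flagged
#' acid-producing with probability `p_acid`; every taxon draws a pH tolerance
#' (a non-acid producer dies when its flask pH falls below its tolerance).
#'
#' Uses the current R RNG stream; seed with `set.seed()` (or let
#' [simulate_study()] do it).
#'
#' @param params A [sim_params()] object.
#' @return data.frame with columns `taxon_id`, `kingdom`, `acid_flag`,
#'   `rel_abundance` (sums to 1), `tolerance`.
#' @export
make_pool <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  nb <- params$n_taxa_bacteria
  nf <- params$n_taxa_fungi
  n <- nb + nf
  if (n < 1) stop("simulation needs at least one taxon", call. = FALSE)
  taxon_id <- c(if (nb) sprintf("BASV_%04d", seq_len(nb)),
                if (nf) sprintf("FASV_%04d", seq_len(nf)))
  kingdom <- rep(c("bacteria", "fungi"), c(nb, nf))
  acid <- logical(n)
  if (nb) acid[seq_len(nb)] <- stats::runif(nb) < params$p_acid
  w <- stats::rlnorm(n, meanlog = 0, sdlog = params$pool_abundance_shape)
  tol <- numeric(n)
  if (nb) tol[seq_len(nb)] <-
      stats::rnorm(nb, params$tolerance_mean, params$tolerance_sd)
  if (nf) tol[nb + seq_len(nf)] <-
      stats::rnorm(nf, params$tolerance_mean_fungi, params$tolerance_sd_fungi)
  data.frame(taxon_id = taxon_id, kingdom = kingdom, acid_flag = acid,
             rel_abundance = w / sum(w), tolerance = tol,
             stringsAsFactors = FALSE)
}

#' Assemble a flask from the pool
#'
#' Multinomial draw of `round(density_per_ml * volume_ml)` individuals from
#' the pool relative abundances.
#'
#' @param pool A pool from [make_pool()].
#' @param volume_ml Flask volume (> 0).
#' @param params A [sim_params()] object.
#' @return Integer-valued abundance vector (one entry per pool taxon) summing
#'   to the number of assembled individuals.
#' @export
assemble_flask <- function(pool, volume_ml, params) {
  if (!is.numeric(volume_ml) || length(volume_ml) != 1 || volume_ml <= 0)
    stop("`volume_ml` must be a single positive number", call. = FALSE)
  size <- round(params$density_per_ml * volume_ml)
  as.numeric(stats::rmultinom(1, size = size, prob = pool$rel_abundance))
}

#' Deterministic pH trajectory
#'
#' Logistic fall from `ph_start` to a flask-specific floor around a
#' flask-specific midpoint, then linear recovery from `ph_recovery_day` at
#' `ph_recovery_rate` per day, capped at `ph_end`. With `ph_crash = FALSE`
#' the trajectory is flat at `ph_start`.
#'
#' @param day Numeric vector of days.
#' @param params A [sim_params()] object.
#' @param fall_mid,floor Flask-specific crash midpoint and floor; defaults to
#'   the population values.
#' @return Numeric vector of pH values (noise-free).
#' @export
ph_trajectory <- function(day, params, fall_mid = params$ph_fall_mid,
                          floor = params$ph_floor) {
  if (!params$ph_crash) return(rep(params$ph_start, length(day)))
  fall <- floor + (params$ph_start - floor) *
    stats::plogis((fall_mid - day) / params$ph_fall_scale)
  rise <- pmax(day - params$ph_recovery_day, 0) * params$ph_recovery_rate
  pmin(fall + rise, pmax(params$ph_end, fall))
}

#' Initialise the latent state of all flasks
#'
#' One persistent flask per (volume, replicate) lineage; sampling at schedule
#' days is non-destructive in the simulator (statistically equivalent to the
#' destructive design for per-day analyses, and it makes latent extinction
#' and annihilation monotone within a lineage).
#'
#' @param design An [mc_design()].
#' @param pool A pool from [make_pool()].
#' @param params A [sim_params()] object.
#' @return A latent state list (class `mc_state`): abundance matrix
#'   (taxa x flasks), alive-taxon logical matrix, flask pH vector, flask
#'   annihilation flags, and flask descriptors.
#' @export
init_state <- function(design, pool, params) {
  flasks <- expand.grid(replicate = seq_len(design$n_replicates),
                        volume_ml = design$volumes_ml,
                        KEEP.OUT.ATTRS = FALSE)[, c("volume_ml", "replicate")]
  nf <- nrow(flasks)
  abund <- vapply(seq_len(nf), function(i)
    assemble_flask(pool, flasks$volume_ml[i], params),
    numeric(nrow(pool)))
  state <- list(
    day = 0L,
    abundance = abund,
    alive = abund > 0,
    flask_alive = rep(TRUE, nf),
    ph = rep(params$ph_start, nf),
    flasks = flasks,
    fall_mid = stats::rnorm(nf, params$ph_fall_mid, params$ph_fall_mid_sd),
    ph_floor = stats::rnorm(nf, params$ph_floor, params$ph_floor_sd),
    death_day = matrix(Inf, nrow(pool), nf),
    annihilation_day = rep(Inf, nf),
    pool = pool,
    params = params)
  state$death_day[!state$alive] <- 0
  class(state) <- "mc_state"
  state
}

#' Advance the latent state by one day
#'
#' Order of events: (i) pH update along the flask trajectory plus noise;
#' (ii) stress deaths — non-acid-producing taxa whose tolerance exceeds the
#' current flask pH die; (iii) demographic deaths with per-day hazard
#' `base_hazard * mult * v^(-gamma_volume)`, plus `collapse_hazard` inside the
#' collapse window; (iv) whole-flask annihilation with the regime-appropriate
#' hazard; (v) multiplicative lognormal noise on surviving abundances.
#' Extinction is irreversible (closed system, no dispersal).
#'
#' @param state A latent state from [init_state()].
#' @param params A [sim_params()] object.
#' @return The updated state, with `day` advanced by one.
#' @export
step_day <- function(state, params) {
  stopifnot(inherits(state, "mc_state"))
  t <- state$day + 1L
  nf <- nrow(state$flasks)
  ntax <- nrow(state$pool)
  v <- state$flasks$volume_ml

  state$ph <- ph_trajectory(t, params, state$fall_mid, state$ph_floor) +
    stats::rnorm(nf, 0, params$ph_noise_sd)

  # per-taxon per-flask death probability for this day
  mult <- ifelse(state$pool$kingdom == "bacteria" & !state$pool$acid_flag,
                 params$vuln_hazard_mult, 1)
  haz_v <- params$base_hazard * v^(-params$gamma_volume)
  if (params$collapse_hazard > 0 &&
      t > params$collapse_start && t <= params$collapse_end)
    haz_v <- haz_v + params$collapse_hazard
  haz <- outer(mult, haz_v)          # taxa x flasks
  haz[haz > 1] <- 1

  dies <- matrix(stats::runif(ntax * nf), ntax, nf) < haz
  if (params$ph_crash) {
    stressed <- (!state$pool$acid_flag) &
      outer(state$pool$tolerance, state$ph, ">")
    dies <- dies | stressed
  }
  newly_dead <- state$alive & dies
  state$alive[newly_dead] <- FALSE
  state$death_day[newly_dead] <- t

  # whole-flask annihilation
  ann_h <- numeric(nf)
  if (t > params$ann_phase3_start) {
    ann_h[] <- params$annihilation_hazard_phase3
  } else if (t > params$ann_phase2_start) {
    ann_h[] <- params$annihilation_hazard_phase2
  }
  annihilated <- state$flask_alive & (stats::runif(nf) < ann_h)
  if (any(annihilated)) {
    state$flask_alive[annihilated] <- FALSE
    state$annihilation_day[annihilated] <- t
    still <- state$alive[, annihilated, drop = FALSE]
    state$death_day[, annihilated][still] <- t
    state$alive[, annihilated] <- FALSE
  }

  noise <- matrix(exp(stats::rnorm(ntax * nf, 0, params$noise_sigma)),
                  ntax, nf)
  state$abundance <- state$abundance * noise * state$alive
  state$day <- t
  state
}

#' Sequence a sample by multinomial subsampling
#'
#' @param abundance Non-negative abundance vector (true community).
#' @param seq_depth Number of reads to draw.
#' @return Integer count vector summing to `seq_depth`, or all zeros when the
#'   community is empty (annihilated flask).
#' @export
sequence_sample <- function(abundance, seq_depth) {
  if (!is.numeric(seq_depth) || length(seq_depth) != 1 || seq_depth < 0)
    stop("`seq_depth` must be a single non-negative number", call. = FALSE)
  if (any(abundance < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(abundance) == 0 || seq_depth == 0) return(integer(length(abundance)))
  as.integer(stats::rmultinom(1, size = seq_depth,
                              prob = abundance / sum(abundance)))
}

#' Simulate a full microcosm monitoring study
#'
#' Draws a species pool, assembles one flask lineage per (volume, replicate),
#' advances the latent state day by day, and sequences every flask at each
#' schedule day, plus one day-0 species-pool reference sample sequenced
#' directly from the pool.
#'
#' @param design An [mc_design()].
#' @param params A [sim_params()] object.
#' @param seed Integer RNG seed; identical seed and parameters give
#'   identical output.
#' @return Object of class `mc_sim`: list with `features` (taxa x samples
#'   integer count matrix, first column the pool reference `POOL`),
#'   `metadata` (sample_id, volume_ml, day, replicate, pH; day 0 = pool),
#'   `pool` (the ground-truth pool table), and `truth` (death-day matrix,
#'   annihilation days, pH log, flask table, seed).
#' @export
simulate_study <- function(design = mc_design(), params = sim_params(),
                           seed = 1L) {
  stopifnot(inherits(design, "mc_design"), inherits(params, "sim_params"))
  set.seed(as.integer(seed))
  pool <- make_pool(params)
  state <- init_state(design, pool, params)
  nf <- nrow(state$flasks)
  sched <- design$schedule_days

  n_samp <- nf * length(sched)
  counts <- matrix(0L, nrow(pool), n_samp + 1L)
  meta <- data.frame(sample_id = character(n_samp + 1L),
                     volume_ml = NA_real_, day = NA_integer_,
                     replicate = NA_integer_, pH = NA_real_,
                     stringsAsFactors = FALSE)
  counts[, 1L] <- sequence_sample(pool$rel_abundance, params$seq_depth)
  meta[1L, ] <- list("POOL", NA_real_, 0L, NA_integer_, params$ph_start)

  ph_log <- matrix(NA_real_, design$total_days, nf)
  col <- 1L
  for (t in seq_len(design$total_days)) {
    state <- step_day(state, params)
    ph_log[t, ] <- state$ph
    if (t %in% sched) {
      for (f in seq_len(nf)) {
        col <- col + 1L
        counts[, col] <- sequence_sample(state$abundance[, f],
                                         params$seq_depth)
        meta[col, ] <- list(
          sprintf("S%04d", col - 1L),
          state$flasks$volume_ml[f], t, state$flasks$replicate[f],
          round(state$ph[f], 3))
      }
    }
  }
  dimnames(counts) <- list(pool$taxon_id, meta$sample_id)
  structure(list(
    features = counts,
    metadata = meta,
    pool = pool,
    truth = list(death_day = state$death_day,
                 annihilation_day = state$annihilation_day,
                 ph = ph_log,
                 flasks = state$flasks,
                 fall_mid = state$fall_mid,
                 ph_floor = state$ph_floor,
                 seed = as.integer(seed)),
    params = params,
    design = design), class = "mc_sim")
}

#' @export
print.mc_sim <- function(x, ...) {
  cat(sprintf("Simulated microcosm study: %d taxa x %d samples (+1 pool)\n",
              nrow(x$features), ncol(x$features) - 1L))
  cat(sprintf("  annihilated flasks: %d / %d\n",
              sum(is.finite(x$truth$annihilation_day)),
              length(x$truth$annihilation_day)))
  invisible(x)
}
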