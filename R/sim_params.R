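#' Simulator parameters
#'
#' Parameters of the stochastic closed-microcosm community model. The default
#' preset emulates the fermented-vegetable microcosm study design: a shared
#' well-mixed species pool of 783 bacterial and 889 fungal ASVs, saturating
#' assembly so that initial richness is volume-independent, a volume-scaled
#' demographic extinction hazard, a pH crash around day 5-7 that selectively
#' kills acid-intolerant taxa (first mass extinction), a late resource
#' collapse plus whole-flask annihilation surge around day 40 (second mass
#' extinction), and multinomial sequencing subsampling.
#'
#' Hazards are per-day probabilities. A taxon's demographic hazard in a flask
#' of volume v (mL) is `base_hazard * mult * v^(-gamma_volume)`, where `mult`
#' is `vuln_hazard_mult` for acid-intolerant (non-acid-producing) bacteria and
#' 1 otherwise. Acid-producing bacteria are exempt from pH stress; fungi are
#' non-acid-producing but draw low pH tolerances, so they survive the crash.
#'
#' @param n_taxa_bacteria,n_taxa_fungi Pool sizes per kingdom.
#' @param p_acid Fraction of bacterial taxa flagged acid-producing.
#' @param pool_abundance_shape Lognormal sigma of pool relative abundances.
#' @param density_per_ml Individuals per mL at assembly. The default (1e5) is
#'   deliberately saturating: every taxon likely to be detectable at
#'   `seq_depth` is present even in the smallest flask, so day-1 richness
#'   carries no volume signal.
#' @param gamma_volume Exponent of the volume dependence of the extinction
#'   hazard (>= 0; 0 switches the volume effect off).
#' @param base_hazard Baseline per-day extinction probability at v = 1 mL for
#'   demographically robust taxa.
#' @param vuln_hazard_mult Hazard multiplier for acid-intolerant bacteria.
#' @param ph_start,ph_floor,ph_end pH trajectory anchors.
#' @param ph_fall_mid,ph_fall_scale Midpoint (day) and logistic scale of the
#'   pH fall; per-flask midpoints are jittered with sd `ph_fall_mid_sd`.
#' @param ph_fall_mid_sd,ph_floor_sd Between-flask sd of the crash timing and
#'   depth.
#' @param ph_recovery_day,ph_recovery_rate Onset (day) and linear rate
#'   (pH units/day) of the pH recovery, capped at `ph_end`.
#' @param ph_noise_sd Daily measurement/process noise on pH.
#' @param tolerance_mean,tolerance_sd Bacterial pH-tolerance distribution: a
#'   non-acid-producing taxon dies when its flask pH falls below its drawn
#'   tolerance.
#' @param tolerance_mean_fungi,tolerance_sd_fungi Fungal tolerance
#'   distribution (low: fungi withstand the crash).
#' @param ph_crash Logical; FALSE holds pH flat at `ph_start` and disables all
#'   stress deaths (used by the null preset).
#' @param collapse_start,collapse_end,collapse_hazard Late resource collapse:
#'   extra per-day hazard applied to every surviving taxon on days
#'   `(collapse_start, collapse_end]`.
#' @param ann_phase2_start,annihilation_hazard_phase2 Onset day and per-day
#'   whole-flask annihilation hazard of the early annihilation regime.
#' @param ann_phase3_start,annihilation_hazard_phase3 Onset day and hazard of
#'   the late regime.
#' @param noise_sigma Daily multiplicative lognormal noise on abundances.
#' @param seq_depth Reads per sequenced sample.
#' @return Object of class `sim_params`.
#' @seealso [sim_params_null()], [sim_params_small()], [simulate_study()]
#' @export
sim_params <- function(n_taxa_bacteria = 783L,
                       n_taxa_fungi = 889L,
                       p_acid = 0.30,
                       pool_abundance_shape = 1.5,
                       density_per_ml = 1e5,
                       gamma_volume = 0.5,
                       base_hazard = 0.02,
                       vuln_hazard_mult = 7.5,
                       ph_start = 6.2,
                       ph_floor = 3.2,
                       ph_end = 6.0,
                       ph_fall_mid = 5,
                       ph_fall_scale = 0.8,
                       ph_fall_mid_sd = 0.45,
                       ph_floor_sd = 0.15,
                       ph_recovery_day = 40,
                       ph_recovery_rate = 0.3,
                       ph_noise_sd = 0.05,
                       tolerance_mean = 3.8,
                       tolerance_sd = 0.25,
                       tolerance_mean_fungi = 2.5,
                       tolerance_sd_fungi = 0.3,
                       ph_crash = TRUE,
                       collapse_start = 36,
                       collapse_end = 42,
                       collapse_hazard = 0.15,
                       ann_phase2_start = 30,
                       annihilation_hazard_phase2 = 0.01,
                       ann_phase3_start = 42,
                       annihilation_hazard_phase3 = 0.10,
                       noise_sigma = 0.25,
                       seq_depth = 20000L) {
  p <- list(n_taxa_bacteria = as.integer(n_taxa_bacteria),
            n_taxa_fungi = as.integer(n_taxa_fungi),
            p_acid = p_acid,
            pool_abundance_shape = pool_abundance_shape,
            density_per_ml = density_per_ml,
            gamma_volume = gamma_volume,
            base_hazard = base_hazard,
            vuln_hazard_mult = vuln_hazard_mult,
            ph_start = ph_start, ph_floor = ph_floor, ph_end = ph_end,
            ph_fall_mid = ph_fall_mid, ph_fall_scale = ph_fall_scale,
            ph_fall_mid_sd = ph_fall_mid_sd, ph_floor_sd = ph_floor_sd,
            ph_recovery_day = ph_recovery_day,
            ph_recovery_rate = ph_recovery_rate,
            ph_noise_sd = ph_noise_sd,
            tolerance_mean = tolerance_mean, tolerance_sd = tolerance_sd,
            tolerance_mean_fungi = tolerance_mean_fungi,
            tolerance_sd_fungi = tolerance_sd_fungi,
            ph_crash = isTRUE(ph_crash),
            collapse_start = collapse_start, collapse_end = collapse_end,
            collapse_hazard = collapse_hazard,
            ann_phase2_start = ann_phase2_start,
            annihilation_hazard_phase2 = annihilation_hazard_phase2,
            ann_phase3_start = ann_phase3_start,
            annihilation_hazard_phase3 = annihilation_hazard_phase3,
            noise_sigma = noise_sigma,
            seq_depth = as.integer(seq_depth))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$n_taxa_bacteria + p$n_taxa_fungi < 1)
    stop("simulation needs at least one taxon", call. = FALSE)
  probs <- c(p$p_acid, p$base_hazard, p$collapse_hazard,
             p$annihilation_hazard_phase2, p$annihilation_hazard_phase3)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p$gamma_volume < 0) stop("`gamma_volume` must be >= 0", call. = FALSE)
  if (p$seq_depth <= 0) stop("`seq_depth` must be positive", call. = FALSE)
  if (p$density_per_ml <= 0)
    stop("`density_per_ml` must be positive", call. = FALSE)
  invisible(p)
}

#' Null (no-structure) simulator preset
#'
#' Volume effect, pH crash, resource collapse and annihilation all switched
#' off: flasks are exchangeable across volumes, so per-day SAR tests are
#' exercised under their null. Used to calibrate the false-detection rate of
#' positive SAR classification.
#'
#' @param ... Overrides passed to [sim_params()].
#' @export
sim_params_null <- function(...) {
  args <- utils::modifyList(
    list(gamma_volume = 0, ph_crash = FALSE, collapse_hazard = 0,
         annihilation_hazard_phase2 = 0, annihilation_hazard_phase3 = 0),
    list(...))
  do.call(sim_params, args)
}

#' Scaled-down simulator preset for fast tests
#'
#' Same mechanisms as the default preset with a smaller pool and shallower
#' sequencing; keeps unit tests fast. Assembly density is still saturating
#' relative to the reduced pool.
#'
#' @param ... Overrides passed to [sim_params()].
#' @export
sim_params_small <- function(...) {
  args <- utils::modifyList(
    list(n_taxa_bacteria = 120L, n_taxa_fungi = 130L,
         density_per_ml = 2e4, seq_depth = 5000L),
    list(...))
  do.call(sim_params, args)
}

#' Scripted event windows of a parameter set
#'
#' Day windows implied by the generator's regime switches, used by
#' pattern-recovery tests: `crash` and `collapse` bracket the two scripted
#' mass-extinction episodes (the pH crash; the annihilation surge plus
#' resource collapse — flask annihilation jumps the per-flask extinction
#' rate to 1, so the episode starts at the annihilation onset), and
#' `stable` is the post-crash, pre-collapse span in which the re-built
#' volume signal is expected to yield positive SARs.
#'
#' `crash` brackets all days over which the pH-crash extinction jump can
#' register, while `crash_core` is its centre — the days on which the crash
#' actively randomises richness across flasks and the SAR is expected to be
#' absent (tolerances are crossed about one day after the pH-fall midpoint,
#' with under a day of between-flask spread).
#'
#' @param params A [sim_params()] object.
#' @return List with elements `crash`, `crash_core`, `collapse` and
#'   `stable`, each `c(first, last)` day, or `NULL` when the episode is
#'   disabled.
#' @export
scripted_windows <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  crash <- if (params$ph_crash)
    c(floor(params$ph_fall_mid), ceiling(params$ph_fall_mid + 3)) else NULL
  crash_core <- if (params$ph_crash)
    c(round(params$ph_fall_mid + 1), round(params$ph_fall_mid + 2)) else NULL
  collapse <- if (params$collapse_hazard > 0 ||
                  params$annihilation_hazard_phase2 > 0 ||
                  params$annihilation_hazard_phase3 > 0)
    c(min(params$collapse_start, params$ann_phase2_start),
      params$collapse_end + 4) else NULL
  stable <- c(params$ann_phase2_start - 8, params$ann_phase2_start)
  list(crash = crash, crash_core = crash_core, collapse = collapse,
       stable = stable)
}
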