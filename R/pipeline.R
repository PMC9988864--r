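#' Read a pipeline configuration file
#'
#' JSON (via jsonlite) is the canonical config format; YAML is accepted when
#' the `yaml` package is available. See [default_config()] for the schema.
#'
#' @param path Config file (`.json`, `.yaml`/`.yml`).
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the `yaml` package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Default pipeline configuration
#'
#' @return Named list: `design` (volumes_ml, n_replicates, schedule bounds),
#'   `alpha`, `rare_fraction`, `mass_extinction_delta`, `log_base`,
#'   `drop_annihilated`, `seed`, plus optional `input` paths
#'   (features/metadata/traits TSVs) — when absent, the simulator supplies
#'   the data (`simulate = TRUE`).
#' @export
default_config <- function() {
  list(design = list(volumes_ml = c(10, 20, 50, 100, 250, 500, 1000),
                     n_replicates = 3, daily_until = 10,
                     step2_until = 30, step5_until = 60),
       simulate = TRUE,
       alpha = 0.05,
       rare_fraction = 1e-5,
       mass_extinction_delta = 0.10,
       log_base = 10,
       drop_annihilated = FALSE,
       seed = 1)
}

config_design <- function(config) {
  d <- config$design
  if (is.null(d)) return(mc_design())
  mc_design(volumes_ml = d$volumes_ml %||% c(10, 20, 50, 100, 250, 500, 1000),
            n_replicates = d$n_replicates %||% 3,
            schedule_days = if (!is.null(d$schedule_days)) d$schedule_days
            else build_schedule(d$daily_until %||% 10,
                                d$step2_until %||% 30,
                                d$step5_until %||% 60),
            total_days = d$total_days %||% (d$step5_until %||% 60))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  problems <- character(0)
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(is.numeric(config$alpha %||% 0.05) &&
        config$alpha > 0 && config$alpha < 1,
      "alpha must be in (0, 1)")
  chk((config$rare_fraction %||% 1e-5) >= 0 && config$rare_fraction < 1,
      "rare_fraction must be in [0, 1)")
  chk((config$mass_extinction_delta %||% 0.1) > 0,
      "mass_extinction_delta must be positive")
  if (!is.null(config$input)) {
    for (f in c("features", "metadata")) {
      chk(!is.null(config$input[[f]]), paste0("input$", f, " path missing"))
      if (!is.null(config$input[[f]]))
        chk(file.exists(config$input[[f]]),
            paste0("input$", f, " file not found: ", config$input[[f]]))
    }
  }
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> preprocess -> SAR scan -> extinction/annihilation ->
#' phase dynamics -> traits, writing one tidy TSV per result into
#' `out_dir` together with a JSON run manifest (seed, config, package
#' version). Deterministic given the seed.
#'
#' @param config Named list (see [default_config()]) or path to a
#'   JSON/YAML config file.
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @return Invisible list with every computed result table.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(default_config(), config)
  validate_config(config)
  design <- config_design(config)
  seed <- as.integer(config$seed %||% 1)

  if (!is.null(config$input)) {
    features <- read_feature_table(config$input$features)
    metadata <- read_metadata(config$input$metadata)
    traits <- if (!is.null(config$input$traits))
      read_traits(config$input$traits) else NULL
    sim <- NULL
  } else {
    params <- do.call(sim_params, config$sim_params %||% list())
    sim <- simulate_study(design, params, seed = seed)
    features <- sim$features
    metadata <- sim$metadata
    traits <- sim$pool[c("taxon_id", "kingdom", "acid_flag")]
  }

  prep <- preprocess_tables(features, threshold_fraction = config$rare_fraction,
                            seed = seed)
  dataset <- join_dataset(prep$table,
                          metadata[metadata$sample_id %in%
                                     colnames(prep$table), ])

  scan <- sar_scan(dataset, alpha = config$alpha,
                   log_base = config$log_base,
                   drop_annihilated = isTRUE(config$drop_annihilated))
  occurrence <- summarize_occurrence(scan, design)

  records <- extinction_records(dataset)
  ann <- annihilation_rates(dataset)
  corr <- correlate_extinction_volume(records, alpha = config$alpha)
  series <- mean_extinction_series(records)
  mass_days <- detect_mass_extinctions(series$day, series$mean_rate,
                                       delta = config$mass_extinction_delta)

  ph_series <- stats::aggregate(pH ~ day, data = metadata[metadata$day > 0, ],
                                FUN = mean, na.action = stats::na.omit)
  seg <- segment_phases(ph_series$day, ph_series$pH)
  bell_ph <- fit_bell(ph_series$day, ph_series$pH)
  bell_ann <- fit_bell(ann$day, ann$annihilation_rate)
  phase_ext <- phase_mean_extinction(records, seg)
  shan <- shannon_table(dataset)
  wilcox <- if (nrow(seg) >= 2) phase_diversity_test(shan, seg) else NULL
  nmds <- tryCatch({
    bc <- bray_curtis(dataset$features[, dataset$metadata$day > 0,
                                       drop = FALSE])
    nmds_ordination(bc, seed = seed)
  }, error = function(e) NULL)
  strat <- if (!is.null(traits))
    tryCatch(stratified_extinction(dataset, traits), error = function(e) NULL)
  else NULL

  results <- list(design = design, scan = scan, occurrence = occurrence,
                  extinction_records = records, annihilation = ann,
                  extinction_volume_corr = corr,
                  mean_extinction = series, mass_extinction_days = mass_days,
                  phases = seg, bell_ph = bell_ph, bell_annihilation = bell_ann,
                  phase_mean_extinction = phase_ext, shannon = shan,
                  wilcoxon = wilcox, nmds = nmds,
                  stratified_extinction = strat,
                  dropped_taxa = prep$dropped, sim = sim)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) if (!is.null(x))
      utils::write.table(x, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(as.data.frame(scan), "sar_fits.tsv")
    wt(data.frame(timepoint_fraction = occurrence$timepoint_fraction,
                  period_fraction = occurrence$period_fraction,
                  period_days = occurrence$period_days,
                  positive_days = paste(occurrence$positive_days,
                                        collapse = ","),
                  negative_days = paste(occurrence$negative_days,
                                        collapse = ",")),
       "occurrence.tsv")
    wt(records, "extinction_records.tsv")
    wt(ann, "annihilation.tsv")
    wt(corr, "corr_scan.tsv")
    wt(data.frame(day = mass_days), "mass_extinction_days.tsv")
    wt(as.data.frame(seg), "phases.tsv")
    bf <- function(b, what) data.frame(
      series = what, a = b$a, mu = b$mu, sigma = b$sigma, d = b$d,
      r_squared = b$r_squared, p_value = b$p_value, converged = b$converged)
    wt(rbind(bf(bell_ph, "pH"), bf(bell_ann, "annihilation_rate")),
       "bell_fits.tsv")
    wt(phase_ext, "phase_mean_extinction.tsv")
    wt(shan, "shannon.tsv")
    wt(wilcox, "wilcoxon.tsv")
    if (!is.null(nmds))
      wt(data.frame(sample_id = rownames(nmds$points), nmds$points,
                    stress = nmds$stress), "nmds_coords.tsv")
    wt(strat, "stratified_extinction.tsv")
    if (!is.null(sim)) write_simulation(sim, file.path(out_dir, "sim"))
    manifest <- list(package = "microsar",
                     version = as.character(utils::packageVersion("microsar")),
                     seed = seed,
                     timestamp = format(Sys.time(), tz = "UTC"),
                     config = config)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}
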