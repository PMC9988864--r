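#' Extinction rates stratified by acid-producing status
#'
#' Bacterial pool taxa are split into acid-producing and non-acid-producing
#' groups by the trait map, and per-sample extinction rates are computed for
#' each group against that group's pool subset. Taxa with unknown flags are
#' excluded (their count is reported via attribute `n_unknown`); groups with
#' an empty pool subset are omitted with a warning.
#'
#' @param dataset An `mc_dataset`.
#' @param traits Trait map data.frame (`taxon_id`, `kingdom`, `acid_flag`;
#'   see [read_traits()]).
#' @param pool Pool taxon ids; defaults to [pool_taxa()].
#' @return data.frame: extinction records (as in [extinction_records()])
#'   plus a `group` column (`acid` / `non_acid`).
#' @export
stratified_extinction <- function(dataset, traits,
                                  pool = pool_taxa(dataset)) {
  bact <- traits[traits$kingdom == "bacteria", ]
  if (nrow(bact) == 0)
    stop("trait map covers no bacterial taxa", call. = FALSE)
  unknown <- bact$taxon_id[is.na(bact$acid_flag)]
  groups <- list(
    acid = intersect(pool, bact$taxon_id[which(bact$acid_flag)]),
    non_acid = intersect(pool, bact$taxon_id[which(!bact$acid_flag)]))
  rows <- lapply(names(groups), function(g) {
    sub_pool <- groups[[g]]
    if (length(sub_pool) == 0) {
      warning("group '", g, "' has an empty pool subset; omitted",
              call. = FALSE)
      return(NULL)
    }
    rec <- extinction_records(dataset, pool = sub_pool)
    rec$group <- g
    rec
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) attr(out, "n_unknown") <- length(unknown)
  out
}

#' Pearson correlation of trait abundance with volume (forest table)
#'
#' For each trait and each requested day, the Pearson correlation of the
#' trait's relative abundance with flask volume, with a two-sided test and a
#' 95% confidence interval for r via the Fisher z transform (n - 3
#' denominator; days with fewer than 4 samples report r without a CI).
#' Zero-variance traits are flagged `not_assessable`.
#'
#' @param trait_abundance Matrix traits x samples of relative abundances in
#'   [0, 1] (row names = trait ids, column names = sample ids).
#' @param metadata Sample metadata (see [validate_metadata()]).
#' @param days Days to evaluate; defaults to all sampled days.
#' @param alpha Significance level used for the `flag` column.
#' @return data.frame: `trait`, `day`, `n`, `r`, `p_value`, `ci_lo`,
#'   `ci_hi`, `flag`.
#' @export
trait_volume_correlation <- function(trait_abundance, metadata,
                                     days = NULL, alpha = 0.05) {
  if (!is.matrix(trait_abundance) || is.null(rownames(trait_abundance)))
    stop("`trait_abundance` must be a matrix with trait row names",
         call. = FALSE)
  if (any(trait_abundance < 0 | trait_abundance > 1, na.rm = TRUE))
    stop("trait abundances must be relative abundances in [0, 1]",
         call. = FALSE)
  metadata <- validate_metadata(metadata)
  study <- metadata[metadata$day > 0, ]
  if (is.null(days)) days <- sort(unique(study$day))
  rows <- list()
  for (d in days) {
    sub <- study[study$day == d, ]
    ids <- intersect(sub$sample_id, colnames(trait_abundance))
    v <- sub$volume_ml[match(ids, sub$sample_id)]
    for (tr in rownames(trait_abundance)) {
      y <- trait_abundance[tr, ids]
      ok <- is.finite(y) & is.finite(v)
      n <- sum(ok)
      if (n < 3 || stats::var(y[ok]) == 0 || length(unique(v[ok])) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          trait = tr, day = d, n = n, r = NA_real_, p_value = NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, flag = "not_assessable",
          stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(v[ok], y[ok], method = "pearson")
      r <- unname(ct$estimate)
      if (n >= 4 && abs(r) < 1) {
        z <- atanh(r); se <- 1 / sqrt(n - 3)
        ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
      } else ci <- c(NA_real_, NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, day = d, n = n, r = r, p_value = ct$p.value,
        ci_lo = ci[1], ci_hi = ci[2],
        flag = if (ct$p.value < alpha) {
          if (r < 0) "negative" else "positive"
        } else "none",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Toy trait-abundance table from a simulation
#'
#' Builds a trait x sample relative-abundance matrix where each trait's
#' abundance is the summed relative abundance of its carrier taxa, to
#' exercise the trait-correlation path (a stand-in for gene-content
#' inference, which is out of scope).
#'
#' @param sim An `mc_sim` from [simulate_study()].
#' @param carriers Named list mapping trait name to a character vector of
#'   carrier taxon ids; by default one trait per acid flag class.
#' @return Matrix traits x samples of relative abundances.
#' @export
sim_trait_abundance <- function(sim, carriers = NULL) {
  stopifnot(inherits(sim, "mc_sim"))
  if (is.null(carriers)) {
    carriers <- list(
      acid_producers = sim$pool$taxon_id[sim$pool$acid_flag],
      non_acid_bacteria = sim$pool$taxon_id[
        sim$pool$kingdom == "bacteria" & !sim$pool$acid_flag])
  }
  tot <- colSums(sim$features)
  rel <- sweep(sim$features, 2, pmax(tot, 1), "/")
  out <- t(vapply(carriers, function(ids)
    colSums(rel[rownames(rel) %in% ids, , drop = FALSE]),
    numeric(ncol(rel))))
  rownames(out) <- names(carriers)
  out
}
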