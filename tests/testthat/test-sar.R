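test_that("richness counts detected taxa per sample", {
  m <- toy_table()
  expect_identical(unname(richness(m)), c(2L, 2L, 2L))
  m[, 2] <- 0L
  expect_identical(unname(richness(m)[2]), 0L)
  expect_identical(unname(richness(matrix(c(3L, 0L, 1L), 3,
    dimnames = list(letters[1:3], "s")))), 2L)
})

test_that("fit_sar recovers an exact semi-log line", {
  v <- rep(c(10, 20, 50, 100, 250, 500, 1000), each = 3)
  f <- fit_sar(v, 10 + 5 * log10(v))
  expect_equal(f$slope, 5, tolerance = 1e-10)
  expect_equal(f$intercept, 10, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_identical(f$classification, "positive")
})

test_that("degenerate and insufficient inputs are handled", {
  v <- c(10, 100, 1000)
  f <- fit_sar(v, c(7, 7, 7))
  expect_equal(f$slope, 0)
  expect_identical(f$classification, "none")
  expect_error(fit_sar(c(10, 100), c(1, 2)), "insufficient")
  expect_error(fit_sar(c(10, 10, 10), c(1, 2, 3)), "insufficient")
})

test_that("fit_sar agrees with the normal-equations oracle", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(5:25, 1)
    v <- sample(c(10, 20, 50, 100, 250, 500, 1000), n, replace = TRUE)
    if (length(unique(v)) < 2) next
    s <- round(runif(n, 0, 400) + rnorm(n, sd = 20))
    f <- fit_sar(v, s)
    o <- ols_oracle(log10(v), s)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
    expect_equal(f$p_value, o$p_value, tolerance = 1e-10)
  }
})

test_that("classification is invariant to the log base", {
  set.seed(15)
  for (i in 1:25) {
    v <- rep(c(10, 50, 250, 1000), each = 3)
    s <- round(100 + 30 * log10(v) + rnorm(12, sd = 25))
    f10 <- fit_sar(v, s, log_base = 10)
    fe <- fit_sar(v, s, log_base = exp(1))
    expect_identical(f10$classification, fe$classification)
    expect_equal(f10$p_value, fe$p_value, tolerance = 1e-12)
    expect_equal(fe$slope, f10$slope / log(10), tolerance = 1e-10)
  }
})

test_that("sar_scan handles per-day structure and degeneracies", {
  sim <- tiny_sim(seed = 5)
  ds <- join_dataset(sim$features, sim$metadata)
  scan <- sar_scan(ds)
  expect_identical(scan$day, tiny_design()$schedule_days)
  # single-day dataset
  keep <- ds$metadata$day %in% c(0L, 5L)
  ds1 <- join_dataset(ds$features[, keep], ds$metadata[keep, ])
  expect_identical(nrow(sar_scan(ds1)), 1L)
  # a day with every flask annihilated is not assessable
  feats <- ds$features
  feats[, ds$metadata$day == 5] <- 0L
  dsz <- join_dataset(feats, ds$metadata)
  expect_identical(sar_scan(dsz)$classification[
    sar_scan(dsz)$day == 5], "not_assessable")
  # drop_annihilated excludes zero samples from n
  sc <- sar_scan(dsz, drop_annihilated = TRUE)
  expect_identical(sc$classification[sc$day == 5], "not_assessable")
  # aggregate averages over replicates: n = number of volumes
  sca <- sar_scan(ds, aggregate = TRUE)
  expect_true(all(sca$n[sca$classification != "not_assessable"] <=
                  length(tiny_design()$volumes_ml)))
})

test_that("occurrence summary reproduces run-based period coverage", {
  d <- mc_design()
  fits <- data.frame(day = d$schedule_days, classification = "none",
                     stringsAsFactors = FALSE)
  fits$classification[fits$day %in% c(3, 4, 5, 7, 22, 24, 26, 28, 30)] <-
    "positive"
  occ <- summarize_occurrence(fits, d)
  expect_equal(occ$timepoint_fraction, 9 / 26)
  expect_equal(occ$period_fraction, 13 / 60)   # runs 3-5 (3), 7 (1), 22-30 (9)
  expect_identical(occ$period_days, 13L)
  none <- summarize_occurrence(
    data.frame(day = d$schedule_days, classification = "none"), d)
  expect_equal(none$timepoint_fraction, 0)
  expect_equal(none$period_fraction, 0)
})

test_that("occurrence fractions are monotone in added positive days", {
  d <- mc_design()
  set.seed(16)
  for (i in 1:20) {
    base_days <- sort(sample(d$schedule_days, 5))
    more_days <- sort(union(base_days, sample(d$schedule_days, 3)))
    mk <- function(days) summarize_occurrence(
      data.frame(day = d$schedule_days,
                 classification = ifelse(d$schedule_days %in% days,
                                         "positive", "none")), d)
    a <- mk(base_days); b <- mk(more_days)
    expect_gte(b$timepoint_fraction, a$timepoint_fraction)
    expect_gte(b$period_fraction, a$period_fraction)
    expect_true(a$timepoint_fraction >= 0 && a$timepoint_fraction <= 1)
    expect_true(a$period_fraction >= 0 && a$period_fraction <= 1)
  }
})

test_that("negative SARs are reported but never counted as positive", {
  d <- mc_design()
  fits <- data.frame(day = d$schedule_days, classification = "none")
  fits$classification[fits$day %in% c(35, 55)] <- "negative"
  fits$classification[fits$day == 3] <- "positive"
  occ <- summarize_occurrence(fits, d)
  expect_identical(occ$negative_days, c(35L, 55L))
  expect_equal(occ$timepoint_fraction, 1 / 26)
})
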