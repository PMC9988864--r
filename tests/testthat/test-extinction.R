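test_that("extinction_rate follows the pool-loss definition", {
  pool <- sprintf("t%03d", 1:100)
  counts <- setNames(rep(0L, 100), pool)
  counts[1:40] <- 5L
  r <- extinction_rate(counts, pool)
  expect_equal(r$extinction_rate, 0.60)
  expect_identical(r$n_lost, 60L)
  expect_equal(extinction_rate(counts + 1L, pool)$extinction_rate, 0)
  expect_equal(extinction_rate(counts * 0L, pool)$extinction_rate, 1)
  expect_error(extinction_rate(counts, character(0)), "empty")
})

test_that("extinction_records matches per-sample arithmetic", {
  sim <- tiny_sim(seed = 6)
  ds <- join_dataset(sim$features, sim$metadata)
  pool <- pool_taxa(ds)
  rec <- extinction_records(ds)
  expect_identical(nrow(rec), sum(sim$metadata$day > 0))
  i <- sample(nrow(rec), 5)
  for (k in i) {
    manual <- extinction_rate(ds$features[, rec$sample_id[k]], pool)
    expect_equal(rec$extinction_rate[k], manual$extinction_rate)
  }
  expect_true(all(rec$n_lost >= 0 & rec$n_lost <= rec$n_pool))
})

test_that("annihilation is all-zero detection with per-day rates", {
  expect_true(is_annihilated(c(0, 0, 0)))
  expect_false(is_annihilated(c(0, 1, 0)))
  m <- random_table(n_taxa = 3, n_samples = 6, lambda = 10) + 1L
  m[, 5:6] <- 0L
  md <- data.frame(sample_id = colnames(m),
                   volume_ml = rep(c(10, 100, 1000), 2),
                   day = rep(c(1L, 2L), each = 3),
                   replicate = rep(1L, 6))
  ds <- list(features = m, metadata = md)
  ann <- annihilation_rates(ds)
  expect_equal(ann$annihilation_rate, c(0, 2 / 3))
  one <- list(features = m[, 5, drop = FALSE], metadata = md[5, ])
  expect_equal(annihilation_rates(one)$annihilation_rate, 1)
})

test_that("extinction-volume correlation matches the covariance oracle", {
  # exact linear decrease -> r = -1
  rec <- data.frame(day = 1L, volume_ml = c(10, 100, 250, 1000),
                    extinction_rate = 1 - c(10, 100, 250, 1000) / 2000)
  out <- correlate_extinction_volume(rec)
  expect_equal(out$r, -1, tolerance = 1e-12)
  expect_identical(out$flag, "negative")
  # constant rates are not assessable
  recc <- data.frame(day = 1L, volume_ml = c(10, 100, 1000),
                     extinction_rate = 0.5)
  expect_identical(correlate_extinction_volume(recc)$flag, "not_assessable")
  # random instances vs oracle
  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:21, 1)
    rec <- data.frame(day = 1L,
                      volume_ml = sample(c(10, 20, 50, 100, 250, 500, 1000),
                                         n, replace = TRUE),
                      extinction_rate = runif(n))
    if (length(unique(rec$volume_ml)) < 2) next
    out <- correlate_extinction_volume(rec)
    o <- pearson_oracle(rec$volume_ml, rec$extinction_rate)
    expect_equal(out$r, o$r, tolerance = 1e-12)
    expect_equal(out$p_value, o$p_value, tolerance = 1e-10)
  }
})

test_that("correlation is invariant to affine volume rescaling", {
  set.seed(18)
  rec <- data.frame(day = 1L,
                    volume_ml = rep(c(10, 50, 250, 1000), each = 3),
                    extinction_rate = runif(12))
  a <- correlate_extinction_volume(rec)
  rec2 <- rec; rec2$volume_ml <- 0.001 * rec2$volume_ml + 7
  b <- correlate_extinction_volume(rec2)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("mass-extinction detection thresholds absolute jumps", {
  expect_identical(detect_mass_extinctions(1:4, c(.40, .42, .70, .71), .10),
                   3L)
  gentle <- seq(0.1, 0.9, by = 0.05)
  expect_length(detect_mass_extinctions(seq_along(gentle), gentle, .10), 0)
  # unsorted input is sorted by day first
  expect_identical(detect_mass_extinctions(c(3, 1, 2, 4),
                                           c(.70, .40, .42, .71), .10), 3L)
})

test_that("phase means use the sample (n-1) standard deviation", {
  rec <- data.frame(day = c(1, 2, 15, 15), volume_ml = 10,
                    extinction_rate = c(0.5, 0.5, 0.4, 0.6))
  seg <- data.frame(label = c("Phase 1", "Phase 2"),
                    start = c(1, 12), end = c(10, 40))
  pm <- phase_mean_extinction(rec, seg)
  expect_equal(pm$mean, c(0.5, 0.5))
  expect_equal(pm$sd, c(0, 0.1414214), tolerance = 1e-6)
  seg3 <- rbind(seg, data.frame(label = "Phase 3", start = 45, end = 60))
  expect_warning(phase_mean_extinction(rec, seg3), "no sampled records")
})
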