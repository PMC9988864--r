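test_that("fit_bell recovers exact Gaussian parameters", {
  d <- seq(1, 60, by = 2.5)
  y <- 6 + (-2) * exp(-(d - 25)^2 / 200)
  b <- fit_bell(d, y)
  expect_true(b$converged)
  expect_equal(b$a, -2, tolerance = 1e-6)
  expect_equal(b$mu, 25, tolerance = 1e-6)
  expect_equal(b$sigma, 10, tolerance = 1e-6)
  expect_equal(b$d, 6, tolerance = 1e-6)
  expect_equal(b$r_squared, 1, tolerance = 1e-9)
})

test_that("fit_bell degenerate inputs", {
  const <- fit_bell(1:12, rep(3, 12))
  expect_lt(abs(const$a), 1e-6)
  expect_lt(abs(const$r_squared), 1e-6)
  # an inverted bell (pH-style dip) gets negative amplitude
  d <- seq(1, 60, by = 3)
  dip <- fit_bell(d, 6 - 2.5 * exp(-(d - 20)^2 / 90) + rnorm(length(d), 0, .01))
  expect_lt(dip$a, 0)
  expect_error(fit_bell(1:4, 1:4), "at least 5")
})

test_that("fit_bell R2 is near zero on pure noise", {
  set.seed(19)
  r2 <- vapply(1:20, function(i)
    fit_bell(1:26, rnorm(26))$r_squared, numeric(1))
  expect_lt(median(r2), 0.4)
  expect_true(all(r2 <= 1))
})

test_that("segment_phases recovers a scripted three-phase series", {
  days <- mc_design()$schedule_days
  ph <- ifelse(days <= 10, 6.2 - 0.3 * (days - 1),
        ifelse(days <= 40, 3.5, 3.5 + 0.25 * (days - 40)))
  seg <- segment_phases(days, ph)
  expect_identical(seg$label, c("Phase 1", "Phase 2", "Phase 3"))
  expect_identical(seg$start, c(1L, 12L, 45L))
  expect_identical(seg$end, c(10L, 40L, 60L))
  # constant series falls back to one phase
  expect_warning(s1 <- segment_phases(days, rep(4, length(days))),
                 "single phase")
  expect_identical(nrow(s1), 1L)
  # manual override wins
  manual <- data.frame(label = "all", start = 1, end = 60)
  expect_identical(segment_phases(days, ph, phases = manual)$label, "all")
})

test_that("shannon matches closed forms", {
  expect_equal(shannon(c(0, 10, 0)), 0)
  expect_equal(shannon(rep(2, 4)), log(4))
  expect_equal(shannon(c(50, 50, 0)), log(2))
  expect_true(is.na(shannon(c(0, 0))))
  expect_error(shannon(c(-1, 2)), "non-negative")
})

test_that("phase diversity test uses the exact rank-sum null", {
  div <- data.frame(day = c(1, 1, 2, 45, 46, 47),
                    shannon = c(1, 2, 3, 10, 11, 12))
  seg <- data.frame(label = c("Phase 1", "Phase 3"),
                    start = c(1, 45), end = c(10, 60))
  out <- phase_diversity_test(div, seg)
  expect_equal(out$p_value, 0.1)   # 2 / choose(6, 3)
  expect_equal(out$p_value, wilcox_oracle(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-12)
  same <- div; same$shannon <- c(1, 4, 5, 2, 3, 6)
  expect_gt(phase_diversity_test(same, seg)$p_value, 0.65)
})

test_that("rank-sum p-values match the enumeration oracle", {
  set.seed(20)
  for (i in 1:40) {
    x <- runif(sample(3:5, 1))
    y <- runif(sample(3:5, 1))
    div <- data.frame(day = c(rep(1, length(x)), rep(50, length(y))),
                      shannon = c(x, y))
    seg <- data.frame(label = c("A", "B"), start = c(1, 45), end = c(10, 60))
    p <- phase_diversity_test(div, seg)$p_value
    expect_equal(p, wilcox_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("bray_curtis matches the min-sum formula and dist axioms", {
  m <- cbind(a = c(5L, 5L, 0L), b = c(5L, 5L, 0L), c = c(0L, 0L, 9L))
  rownames(m) <- c("t1", "t2", "t3")
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)          # disjoint support
  set.seed(21)
  for (i in 1:30) {
    t <- random_table(n_taxa = 6, n_samples = 4, lambda = 5)
    t[, 1] <- t[, 1] + 1L               # keep totals positive
    dm <- as.matrix(bray_curtis(t))
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm >= 0 & dm <= 1))
    i1 <- sample(4, 1); i2 <- sample(setdiff(1:4, i1), 1)
    if (sum(t[, i1]) > 0 && sum(t[, i2]) > 0)
      expect_equal(dm[i1, i2], bc_oracle(t[, i1], t[, i2]),
                   tolerance = 1e-12)
  }
})

test_that("NMDS separates well-separated clusters at low stress", {
  set.seed(22)
  base <- function(which) {
    p <- rep(1, 30)
    p[which] <- 40
    rmultinom(1, 2000, p / sum(p))[, 1]
  }
  m <- sapply(1:15, function(i) base(((i - 1) %/% 5) * 10 + 1:5))
  rownames(m) <- sprintf("t%02d", 1:30)
  colnames(m) <- sprintf("s%02d", 1:15)
  storage.mode(m) <- "integer"
  ord <- nmds_ordination(bray_curtis(m), seed = 1)
  expect_lt(ord$stress, 0.1)
  grp <- rep(1:3, each = 5)
  centers <- apply(ord$points, 2, function(c) tapply(c, grp, mean))
  d_between <- min(dist(centers))
  d_within <- max(vapply(1:15, function(i)
    sqrt(sum((ord$points[i, ] - centers[grp[i], ])^2)), numeric(1)))
  expect_gt(d_between, d_within)
  # determinism given seed
  ord2 <- nmds_ordination(bray_curtis(m), seed = 1)
  expect_identical(ord$points, ord2$points)
  # degenerate: all-identical samples
  same <- matrix(5L, 4, 3, dimnames = list(paste0("t", 1:4),
                                           paste0("s", 1:3)))
  expect_error(nmds_ordination(bray_curtis(same)), "identical")
})
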