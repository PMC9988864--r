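# Shared fixture builders. Everything is generated in code; no data files.

# small feature table with known structure
toy_table <- function() {
  m <- matrix(c(5L, 0L, 3L,
                0L, 2L, 1L,
                7L, 7L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2", "s3")))
  m
}

# random valid feature table
random_table <- function(n_taxa = 8, n_samples = 5, lambda = 20) {
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

# a tiny but complete simulated study used across tests
tiny_design <- function() {
  mc_design(volumes_ml = c(10, 100, 1000), n_replicates = 2,
            schedule_days = c(1L, 5L, 10L, 20L, 40L, 60L), total_days = 60L)
}

tiny_sim <- function(seed = 7, params = sim_params_small()) {
  simulate_study(tiny_design(), params, seed = seed)
}

# hand-rolled OLS oracle: normal equations, t-test on slope
ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  b <- sum((x - xb) * (y - yb)) / sxx
  a <- yb - b * xb
  res <- y - a - b * x
  sse <- sum(res^2)
  sst <- sum((y - yb)^2)
  s2 <- sse / (n - 2)
  se_b <- sqrt(s2 / sxx)
  tstat <- b / se_b
  list(slope = b, intercept = a,
       r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
       p_value = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE))
}

# hand-rolled Pearson oracle with two-sided t p-value
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE))
}

# brute-force Bray-Curtis for two count vectors
bc_oracle <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# exact two-sided rank-sum p by enumeration of all group assignments
wilcox_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  combs <- utils::combn(n, nx)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  w_all <- apply(combs, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
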