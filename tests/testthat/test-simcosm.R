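test_that("make_pool sizes, flags and normalisation", {
  set.seed(1)
  pool <- make_pool(sim_params())
  expect_identical(nrow(pool), 783L + 889L)
  expect_identical(sum(pool$kingdom == "bacteria"), 783L)
  expect_false(any(pool$acid_flag[pool$kingdom == "fungi"]))
  for (s in 1:20) {
    set.seed(s)
    p <- make_pool(sim_params_small())
    expect_lt(abs(sum(p$rel_abundance) - 1), 1e-12)
  }
  set.seed(2)
  single <- make_pool(sim_params(n_taxa_bacteria = 1, n_taxa_fungi = 0))
  expect_equal(single$rel_abundance, 1.0)
  set.seed(3)
  noacid <- make_pool(sim_params(n_taxa_bacteria = 50, n_taxa_fungi = 0,
                                 p_acid = 0))
  expect_false(any(noacid$acid_flag))
  expect_error(sim_params(n_taxa_bacteria = 0, n_taxa_fungi = 0),
               "at least one taxon")
})

test_that("assemble_flask draws the stated number of individuals", {
  set.seed(4)
  pool <- make_pool(sim_params_small())
  pars <- sim_params_small(density_per_ml = 1000)
  v <- assemble_flask(pool, 10, pars)
  expect_equal(sum(v), 10000)
  one <- data.frame(taxon_id = "t1", kingdom = "bacteria", acid_flag = FALSE,
                    rel_abundance = 1, tolerance = 3)
  expect_equal(assemble_flask(one, 2, pars), 20 * 100)
  expect_error(assemble_flask(pool, -1, pars), "positive")
})

test_that("default assembly density saturates richness across volumes", {
  # analytic occupancy E[S0] = sum_i 1 - (1 - p_i)^N must differ by < 1%
  # between the smallest and largest flask under the default preset
  set.seed(5)
  pars <- sim_params()
  pool <- make_pool(pars)
  occ <- function(N) sum(1 - (1 - pool$rel_abundance)^N)
  s_small <- occ(pars$density_per_ml * 10)
  s_large <- occ(pars$density_per_ml * 1000)
  expect_lt((s_large - s_small) / s_large, 0.01)
})

test_that("step_day without hazards only renormalises", {
  pars <- sim_params_small(base_hazard = 0, ph_crash = FALSE,
                           collapse_hazard = 0,
                           annihilation_hazard_phase2 = 0,
                           annihilation_hazard_phase3 = 0)
  set.seed(6)
  pool <- make_pool(pars)
  st <- init_state(tiny_design(), pool, pars)
  rich0 <- colSums(st$abundance > 0)
  for (i in 1:15) st <- step_day(st, pars)
  expect_identical(colSums(st$abundance > 0), rich0)
  expect_true(all(st$flask_alive))
})

test_that("per-day extinction count decreases with volume when gamma > 0", {
  # closed-form expectation: E[deaths] = n_alive * base_hazard * v^(-gamma)
  pars <- sim_params_small(ph_crash = FALSE, base_hazard = 0.2,
                           vuln_hazard_mult = 1, gamma_volume = 0.5,
                           annihilation_hazard_phase2 = 0,
                           annihilation_hazard_phase3 = 0)
  set.seed(7)
  pool <- make_pool(pars)
  des <- mc_design(volumes_ml = c(10, 100, 1000), n_replicates = 10,
                   schedule_days = 1L, total_days = 1L)
  deaths <- matrix(NA_real_, 30, 3)
  for (r in 1:30) {
    st <- init_state(des, pool, pars)
    alive0 <- colSums(st$alive)
    st <- step_day(st, pars)
    d <- alive0 - colSums(st$alive)
    deaths[r, ] <- tapply(d, st$flasks$volume_ml, mean)
  }
  emp <- colMeans(deaths)
  expected <- nrow(pool) * pars$base_hazard * c(10, 100, 1000)^-0.5
  expect_true(all(diff(emp) < 0))
  expect_equal(emp, expected, tolerance = 0.15)
})

test_that("acid-intolerant taxa are eliminated by the pH crash", {
  pars <- sim_params_small(base_hazard = 0, annihilation_hazard_phase2 = 0,
                           annihilation_hazard_phase3 = 0,
                           collapse_hazard = 0)
  set.seed(8)
  pool <- make_pool(pars)
  st <- init_state(tiny_design(), pool, pars)
  for (i in 1:20) st <- step_day(st, pars)
  vulnerable <- pool$kingdom == "bacteria" & !pool$acid_flag &
    pool$tolerance > max(st$ph_floor) + 0.3
  expect_false(any(st$alive[vulnerable, ]))
})

test_that("sequence_sample contracts", {
  expect_equal(sequence_sample(c(0, 4, 0), 5000), c(0L, 5000L, 0L))
  expect_identical(sequence_sample(c(0, 0, 0), 5000), c(0L, 0L, 0L))
  expect_error(sequence_sample(c(1, 2), -3), "non-negative")
  expect_error(sequence_sample(c(-1, 2), 10), "non-negative")
  # multinomial mean: uniform 10 taxa, depth 1e4 -> per-taxon mean 1000
  set.seed(9)
  reps <- vapply(1:1000, function(i) sequence_sample(rep(1, 10), 1e4)[1],
                 integer(1))
  se <- sqrt(1e4 * 0.1 * 0.9) / sqrt(1000)
  expect_lt(abs(mean(reps) - 1000), 3 * se)
})

test_that("simulate_study emits the full design plus a pool sample", {
  sim <- tiny_sim()
  des <- tiny_design()
  expect_identical(ncol(sim$features), nrow(enumerate_samples(des)) + 1L)
  expect_identical(sim$metadata$day[1], 0L)
  one <- simulate_study(mc_design(volumes_ml = 50, n_replicates = 1,
                                  schedule_days = 2L, total_days = 2L),
                        sim_params_small(), seed = 1)
  expect_identical(ncol(one$features), 2L)
})

test_that("simulation is deterministic given the seed", {
  a <- tiny_sim(seed = 123)
  b <- tiny_sim(seed = 123)
  expect_identical(a$features, b$features)
  expect_identical(a$metadata, b$metadata)
  c <- tiny_sim(seed = 124)
  expect_false(identical(a$features, c$features))
})

test_that("latent extinction is monotone and detection only loses taxa", {
  sim <- tiny_sim(seed = 31)
  des <- tiny_design()
  fl <- sim$truth$flasks
  for (f in seq_len(nrow(fl))) {
    for (d in des$schedule_days) {
      ids <- sim$metadata$sample_id[sim$metadata$day == d &
        !is.na(sim$metadata$volume_ml) &
        sim$metadata$volume_ml == fl$volume_ml[f] &
        sim$metadata$replicate == fl$replicate[f]]
      observed <- rownames(sim$features)[sim$features[, ids] > 0]
      alive <- sim$pool$taxon_id[sim$truth$death_day[, f] > d]
      expect_true(all(observed %in% alive))
    }
  }
  # extinct sets never shrink: death days are fixed, so the extinct set at
  # day d is nested in the set at every later day
  dd <- sim$truth$death_day
  for (f in seq_len(ncol(dd))) {
    sizes <- vapply(des$schedule_days, function(d) sum(dd[, f] <= d),
                    numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("latent annihilation rate is monotone non-decreasing", {
  for (s in 1:5) {
    sim <- tiny_sim(seed = 40 + s)
    ann_day <- sim$truth$annihilation_day
    rate <- vapply(tiny_design()$schedule_days,
                   function(d) mean(ann_day <= d), numeric(1))
    expect_true(all(diff(rate) >= 0))
  }
})
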