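test_that("simulation is a deterministic function of the seed", {
  cfg <- sim_config(seed = 11)
  d <- build_design()
  ds1 <- simulate_dataset(d, cfg)
  ds2 <- simulate_dataset(d, cfg)
  expect_identical(ds1, ds2)
  ds3 <- simulate_dataset(d, sim_config(seed = 12))
  expect_false(identical(ds1$growth, ds3$growth))
})

test_that("survivors and deaths account for every individual", {
  ds <- simulate_dataset(build_design(), sim_config(seed = 5))
  m <- ds$metamorphs
  counts <- table(factor(m$unit_id, levels = ds$units$unit_id))
  expect_equal(as.integer(counts), ds$units$n_initial)
  surv <- tapply(m$survived, m$unit_id, sum)[ds$units$unit_id]
  expect_true(all(surv <= ds$units$n_initial))
  # survivors carry both endpoints; non-survivors neither
  expect_true(all(!is.na(m$day_at_metamorphosis[m$survived])))
  expect_true(all(is.na(m$total_length_mm[!m$survived])))
})

test_that("noiseless growth lies exactly on the cell Gompertz curve", {
  cfg <- growth_config(seed = 2, sigma = 0)
  ds <- simulate_dataset(build_design(), cfg)
  g <- growth_data(ds)
  cell <- paste(g$location, g$salinity, g$density, sep = ".")
  mu <- mapply(function(day, cl) {
    oracle_gompertz(day, cfg$S0_true, cfg$gamma_by_cell[[cl]],
                    cfg$alpha_by_cell[[cl]])
  }, g$day, cell)
  expect_equal(g$length, unname(mu), tolerance = 1e-12)
  # and noiseless trajectories never decrease
  for (u in unique(g$unit_id)) {
    y <- g$length[g$unit_id == u][order(g$day[g$unit_id == u])]
    expect_true(all(diff(y) >= 0))
  }
})

test_that("certain survival yields full cups and full panels", {
  cfg <- growth_config(seed = 3)
  ds <- simulate_dataset(build_design(), cfg)
  surv <- tapply(ds$metamorphs$survived, ds$metamorphs$unit_id, sum)
  expect_equal(as.integer(surv[ds$units$unit_id]), ds$units$n_initial)
  expect_equal(nrow(ds$growth), 72L * length(cfg$measurement_days))
})

test_that("growth records stop once a cup has no live individual", {
  # certain death everywhere: deaths are spread uniformly over the larval
  # period, so cups empty out and growth panels must truncate
  cfg <- sim_config(seed = 8, survival_prob_by_cell = cell_values(0))
  ds <- simulate_dataset(build_design(), cfg)
  expect_true(all(!ds$metamorphs$survived))
  g <- ds$growth
  expect_lt(nrow(g), 72L * length(cfg$measurement_days))
  # mortality-only attrition: each unit's recorded days are a prefix of the
  # measurement grid (the live count can only decrease)
  for (u in unique(g$unit_id)) {
    days <- sort(g$day[g$unit_id == u])
    expect_equal(days, cfg$measurement_days[seq_along(days)])
  }
})

test_that("empirical per-cell survival converges to the configured map", {
  cfg <- sim_config(seed = 21, block_sd = 0)
  d <- build_design()
  n_rep <- 150
  tot <- died <- numeric(12)
  names(tot) <- names(died) <- treatment_cells()$cell
  for (r in seq_len(n_rep)) {
    cfg$seed <- 21000L + r
    ds <- simulate_dataset(d, cfg)
    m <- metamorph_data(ds)
    cl <- paste(m$location, m$salinity, m$density, sep = ".")
    tot <- tot + tapply(rep(1, nrow(m)), factor(cl, names(tot)), sum)
    died <- died + tapply(!m$survived, factor(cl, names(tot)), sum)
  }
  p_hat <- 1 - died / tot
  p_true <- cfg$survival_prob_by_cell[names(p_hat)]
  se <- sqrt(p_true * (1 - p_true) / tot)
  expect_true(all(abs(p_hat - p_true) < 4 * se + 1e-12))
})

test_that("the configured density effect reproduces the ~26% survival drop", {
  cfg <- sim_config(seed = 31)
  d <- build_design()
  n_rep <- 300
  rel_drop <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg$seed <- 31000L + r
    ds <- simulate_dataset(d, cfg)
    m <- metamorph_data(ds)
    p_low <- mean(m$survived[m$density == "2"])
    p_high <- mean(m$survived[m$density == "8"])
    rel_drop[r] <- (p_low - p_high) / p_low
  }
  expect_equal(mean(rel_drop), 0.26, tolerance = 0.02)
})
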