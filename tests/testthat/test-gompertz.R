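test_that("the growth curve has the right anchors and asymptote", {
  expect_equal(gompertz_curve(0, S0 = 6, gamma = 0.12, alpha = 0.06), 6)
  # analytic asymptote S0 * exp(gamma/alpha) = 6 e^2
  expect_equal(gompertz_curve(1e6, S0 = 6, gamma = 0.12, alpha = 0.06),
               6 * exp(2), tolerance = 1e-9)
  expect_equal(6 * exp(2), 44.3343, tolerance = 1e-4)
  # half-life of the saturating exponent: t = ln 2 / alpha
  t_half <- log(2) / 0.06
  expect_equal(gompertz_curve(t_half, 6, 0.12, 0.06),
               oracle_gompertz(t_half, 6, 0.12, 0.06))
  expect_equal(gompertz_curve(t_half, 6, 0.12, 0.06), 6 * exp(1))
  expect_error(gompertz_curve(-1, 6, 0.12, 0.06), "negative")
})

test_that("the curve is stable for tiny alpha and approaches S0 e^(gamma t)", {
  t <- c(0, 3, 10)
  expect_equal(gompertz_curve(t, 6, 0.1, 1e-12), 6 * exp(0.1 * t),
               tolerance = 1e-9)
  expect_equal(gompertz_curve(t, 6, 0.1, 1e-300), 6 * exp(0.1 * t),
               tolerance = 1e-9)
})

test_that("curve monotonicities hold across parameter grids", {
  t <- seq(0, 80, by = 0.5)
  for (g in c(0.05, 0.1, 0.2)) for (a in c(0.02, 0.05, 0.1)) {
    expect_true(all(diff(gompertz_curve(t, 6, g, a)) > 0))
  }
  # increasing gamma raises the curve; increasing alpha lowers it (t > 0)
  expect_true(all(gompertz_curve(t[-1], 6, 0.15, 0.05) >
                    gompertz_curve(t[-1], 6, 0.10, 0.05)))
  expect_true(all(gompertz_curve(t[-1], 6, 0.10, 0.08) <
                    gompertz_curve(t[-1], 6, 0.10, 0.05)))
})

test_that("the candidate set is the 16 crossed structures plus one null", {
  specs <- enumerate_model_specs()
  expect_length(specs, 17L)
  nulls <- vapply(specs, function(s) s$gamma == "1" && s$alpha == "1",
                  logical(1))
  expect_equal(sum(nulls), 1L)
  expect_true(nulls[17L])  # null listed last
  expect_equal(sum(!nulls), 16L)
  labels <- vapply(specs, format, "")
  expect_false(anyDuplicated(labels) > 0)
  # the single-parameter structure cannot appear on one side only
  expect_error(gompertz_spec("1", "ADD"), "null")
  expect_error(gompertz_spec("ADD", "1"), "null")
  expect_error(gompertz_spec("L+D", "ADD"), "unknown")
})

test_that("design matrices use treatment coding with the documented sizes", {
  units <- build_design()
  X <- build_design_matrices(gompertz_spec("FULL", "ADD"), units)
  expect_equal(ncol(X$gamma), 12L)
  expect_equal(ncol(X$alpha), 5L)
  X2 <- build_design_matrices(gompertz_spec("LxS", "SxD"), units)
  expect_equal(ncol(X2$gamma), 6L)
  expect_equal(ncol(X2$alpha), 7L)
  X3 <- build_design_matrices(gompertz_spec("1", "1"), units)
  expect_equal(ncol(X3$gamma), 1L)
  # reference row: coastal/fresh/2 has only the intercept set
  ref <- units$location == "coastal" & units$salinity == "fresh" &
    units$density == "2"
  expect_true(all(X$gamma[ref, -1] == 0))
})

test_that("parameter counts match a rank-based coding oracle for all 17 specs", {
  forms <- list("1" = ~1, "ADD" = ~location + salinity + density,
                "LxS" = ~location * salinity + density,
                "SxD" = ~location + salinity * density,
                "FULL" = ~location * salinity * density)
  for (spec in enumerate_model_specs()) {
    expect_equal(count_parameters(spec),
                 2L + oracle_column_count(forms[[spec$gamma]]) +
                   oracle_column_count(forms[[spec$alpha]]),
                 info = format(spec))
    X <- build_design_matrices(spec, build_design())
    expect_equal(count_parameters(spec), 2L + ncol(X$gamma) + ncol(X$alpha))
  }
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(-10, 4, 20), 28 + 40 / 15)
  expect_equal(aicc(-10, 4, 20), 30.66667, tolerance = 1e-5)
  expect_equal(aicc(-10, 0, 20), 20)
  # converges to AIC from above as n grows
  aic <- -2 * (-10) + 2 * 4
  expect_gt(aicc(-10, 4, 30), aic)
  expect_equal(aicc(-10, 4, 1e9), aic, tolerance = 1e-6)
  expect_error(aicc(-10, 4, 5), "n > k \\+ 1")
})

test_that("Akaike weights normalize, preserve order and ignore shifts", {
  expect_equal(akaike_weights(0), 1)
  expect_equal(akaike_weights(c(0, 0)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2, 4))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(w) < 0))
  # invariance to a constant shift of the underlying AICc values
  a <- c(103.2, 100.0, 108.7)
  d1 <- a - min(a)
  d2 <- (a + 55) - min(a + 55)
  expect_equal(akaike_weights(d1), akaike_weights(d2))
  expect_error(akaike_weights(numeric(0)), "empty")
  expect_error(akaike_weights(c(1, 2)), "minimum 0")
})

test_that("the likelihood equals a brute-force Gaussian oracle on a toy series", {
  units <- build_design()[1:3, ]
  toy <- data.frame(
    unit_id = rep(units$unit_id, each = 5),
    location = rep(units$location, each = 5),
    salinity = rep(units$salinity, each = 5),
    density = rep(units$density, each = 5),
    day = rep(c(0, 7, 14, 21, 28), 3)
  )
  set.seed(99)
  toy$length <- 6 * exp(1.5 * (1 - exp(-0.05 * toy$day))) + rnorm(15, 0, 0.4)
  spec <- gompertz_spec("1", "1")
  theta <- c(log(6), log(0.08), log(0.05), log(0.4))
  mu <- oracle_gompertz(toy$day, 6, 0.08, 0.05)
  expect_equal(negative_log_likelihood(theta, spec, toy),
               oracle_gaussian_nll(toy$length, mu, 0.4), tolerance = 1e-10)
  # permutation invariance of the i.i.d. sum
  perm <- sample(nrow(toy))
  expect_equal(negative_log_likelihood(theta, spec, toy[perm, ]),
               negative_log_likelihood(theta, spec, toy))
  # zero residuals: nll = n (log sigma + 0.5 log 2 pi)
  toy$length <- mu
  expect_equal(negative_log_likelihood(theta, spec, toy),
               15 * (log(0.4) + 0.5 * log(2 * pi)), tolerance = 1e-10)
  expect_error(negative_log_likelihood(theta[-1], spec, toy), "length")
})

test_that("the profiled objective's analytic gradient matches finite differences", {
  ds <- simulate_dataset(build_design(), growth_config(seed = 4))
  g <- growth_data(ds)
  spec <- gompertz_spec("ADD", "SxD")
  fd <- metamorph:::gompertz_fit_data(spec, g)
  set.seed(1)
  theta <- c(log(6), log(0.1), rnorm(4, 0, 0.1), log(0.05), rnorm(6, 0, 0.1))
  ana <- metamorph:::nll_profiled_grad(theta, fd)
  num <- oracle_num_grad(function(th) metamorph:::nll_profiled(th, fd), theta)
  expect_equal(ana, num, tolerance = 1e-5)
})
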