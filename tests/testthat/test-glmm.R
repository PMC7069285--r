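test_that("model terms must be hierarchically well formed", {
  expect_silent(glmm_spec("binomial", c("location", "salinity", "density",
                                        "salinity:density")))
  expect_error(glmm_spec("binomial", c("location", "salinity:density")),
               "marginal")
  expect_error(glmm_spec("poisson", c("location", "salinity", "density",
                                      "location:salinity:density")),
               "marginal")
  # component order inside an interaction is canonicalized
  sp <- glmm_spec("poisson", c("density", "salinity", "density:salinity"))
  expect_true("salinity:density" %in% sp$fixed_terms)
})

test_that("the Gaussian family matches the closed-form LMM likelihood", {
  ds <- simulate_dataset(build_design(), sim_config(seed = 41))
  fit <- fit_glmm(glmm_spec("lognormal"), ds)
  fr <- fit$frame
  X <- model.matrix(~ location + salinity + density, fr)
  ll <- oracle_lmm_loglik(fr$log_length, X, fr$block, fit$beta, fit$sigma_b,
                          sigma(fit$fit))
  expect_equal(fit$logLik, ll, tolerance = 1e-8)
  expect_equal(fit$k, length(fit$beta) + 2L)
})

test_that("zero block variance reduces to an independently coded GLM", {
  cfg <- sim_config(seed = 43, block_sd = 0)
  ds <- simulate_dataset(build_design(), cfg)
  fit <- fit_glmm(glmm_spec("binomial"), ds)
  expect_lte(fit$sigma_b, 0.05)
  glm_fit <- glm(cbind(n_survived, n_died) ~ location + salinity + density,
                 data = fit$frame, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(glm_fit)), tolerance = 1e-4)
  # same check for the Poisson endpoint
  fitp <- fit_glmm(glmm_spec("poisson"), ds)
  expect_lte(fitp$sigma_b, 0.05)
  glm_p <- glm(day_at_metamorphosis ~ location + salinity + density,
               data = fitp$frame, family = poisson())
  expect_equal(unname(fitp$beta), unname(coef(glm_p)), tolerance = 1e-4)
})

test_that("degenerate binomial responses raise the separation flag", {
  cfg <- sim_config(seed = 44, survival_prob_by_cell = cell_values(1))
  ds <- simulate_dataset(build_design(), cfg)
  fit <- fit_glmm(glmm_spec("binomial", character(0)), ds)
  expect_true(fit$separation)
})

test_that("non-integer Poisson responses are refused", {
  ds <- simulate_dataset(build_design(), sim_config(seed = 45))
  ds$metamorphs$day_at_metamorphosis <-
    ds$metamorphs$day_at_metamorphosis + 0.5
  expect_error(endpoint_frame(ds, "poisson"), "integer")
})

test_that("the LRT is definitional and refuses non-nested models", {
  ds <- simulate_dataset(build_design(), sim_config(seed = 46))
  fr <- endpoint_frame(ds, "lognormal")
  full <- fit_glmm(glmm_spec("lognormal"), fr)
  red <- fit_glmm(glmm_spec("lognormal", c("location", "salinity")), fr)
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$statistic, 2 * (full$logLik - red$logLik))
  expect_equal(lrt$df, length(full$beta) - length(red$beta))
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, lrt$df, lower.tail = FALSE))
  # identical models: statistic 0, p = 1
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  other <- fit_glmm(glmm_spec("lognormal", c("location", "density")), fr)
  expect_error(likelihood_ratio_test(red, other), "nested")
  pois <- fit_glmm(glmm_spec("poisson"), ds)
  expect_error(likelihood_ratio_test(full, pois), "family")
})

test_that("adding a fixed term never decreases the marginal likelihood", {
  ds <- simulate_dataset(build_design(), sim_config(seed = 47))
  fr <- endpoint_frame(ds, "poisson")
  seqs <- list(character(0), "density", c("location", "density"),
               c("location", "salinity", "density"))
  lls <- vapply(seqs, function(tm)
    fit_glmm(glmm_spec("poisson", tm), fr)$logLik, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("block variance estimates ignore block labels", {
  ds <- simulate_dataset(build_design(), sim_config(seed = 48))
  fr <- endpoint_frame(ds, "lognormal")
  f1 <- fit_glmm(glmm_spec("lognormal"), fr)
  fr2 <- fr
  fr2$block <- factor(7 - as.integer(as.character(fr2$block)))
  f2 <- fit_glmm(glmm_spec("lognormal"), fr2)
  expect_equal(f1$sigma_b, f2$sigma_b, tolerance = 1e-6)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})
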