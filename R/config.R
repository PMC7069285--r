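#' Build a per-cell value map from treatment effects
#'
#' Convenience for specifying cell-level parameters through an effect
#' structure on some link scale: `value(cell) = trans(intercept +
#' sum of matching effects)`. Effect names use the reference-level coding
#' `inland`, `salt`, `d4`, `d8` and interactions joined by `:` (e.g.
#' `"salt:d8"`).
#'
#' @param intercept Value at the reference cell (coastal, fresh, density 2)
#'   on the link scale.
#' @param effects Named numeric vector of link-scale effects.
#' @param trans Inverse link applied to the linear predictor (default
#'   identity).
#' @return Named numeric vector over the 12 cell labels.
#' @examples
#' cell_values(log(0.10), c(inland = -0.1, d8 = -0.2), trans = exp)
#' @export
cell_values <- function(intercept, effects = numeric(0), trans = identity) {
  cells <- treatment_cells()
  ind <- cbind(
    inland = cells$location == "inland",
    salt   = cells$salinity == "salt4ppt",
    d4     = cells$density == "4",
    d8     = cells$density == "8"
  )
  lp <- rep(intercept, nrow(cells))
  for (nm in names(effects)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% colnames(ind))) {
      stop("unknown effect name: ", nm, call. = FALSE)
    }
    on <- Reduce(`&`, lapply(parts, function(p) ind[, p]))
    lp[on] <- lp[on] + effects[[nm]]
  }
  stats::setNames(trans(lp), cells$cell)
}

#' Simulation configuration for the synthetic experiment
#'
#' Bundles everything the generator needs: a shared initial size, per-cell
#' Gompertz rates, residual noise on the cup-mean length, block
#' random-intercept spread, per-cell survival probabilities, per-cell mean
#' age at metamorphosis, per-cell median length at metamorphosis with a
#' log-scale dispersion, the weekly measurement grid, and the seed.
#'
#' The defaults encode the qualitative effect structure reported for this
#' experiment: survival at high density about 26% below low density;
#' coastal metamorphs about 1.7 mm longer than inland; salt water combined
#' with high density adding about 4 days to metamorphosis; gamma varying
#' additively with all three factors and alpha carrying a salinity x
#' density interaction plus a location shift.
#'
#' @param S0_true Shared initial total length at day 0, mm.
#' @param gamma_by_cell,alpha_by_cell Named vectors over the 12 cell
#'   labels: maximum size-specific growth rate and its exponential decay
#'   rate, 1/day. See [cell_values()].
#' @param sigma_resid Gaussian measurement noise sd on cup-mean length, mm.
#' @param block_sd Sd of the Gaussian block random intercept, applied on
#'   each endpoint's link scale (logit for survival, log for age and
#'   length).
#' @param survival_prob_by_cell Per-cell survival probability to
#'   metamorphosis.
#' @param meta_day_mean_by_cell Per-cell mean age at metamorphosis, days
#'   (Poisson mean on the data scale).
#' @param meta_length_mean_by_cell Per-cell median total length at
#'   metamorphosis, mm (log-normal median).
#' @param meta_length_sdlog Log-scale sd of metamorphic length.
#' @param measurement_days Days (from Gosner stage 25, day 0 = first
#'   measurement) on which cup-mean length is recorded; default weekly for
#'   8 weeks.
#' @param seed Integer seed; every random draw in the generator flows from
#'   it.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' round(cfg$survival_prob_by_cell, 2)
#' @export
sim_config <- function(S0_true = 6,
                       gamma_by_cell = cell_values(
                         log(0.10),
                         c(inland = -0.08, salt = -0.08, d4 = -0.10, d8 = -0.22),
                         trans = exp),
                       alpha_by_cell = cell_values(
                         log(0.05),
                         c(inland = 0.03, salt = 0.05, d4 = 0.08, d8 = 0.15,
                           `salt:d4` = 0.05, `salt:d8` = 0.25),
                         trans = exp),
                       sigma_resid = 0.5,
                       block_sd = 0.2,
                       survival_prob_by_cell = cell_values(
                         stats::qlogis(0.90),
                         c(d4 = stats::qlogis(0.80) - stats::qlogis(0.90),
                           d8 = stats::qlogis(0.667) - stats::qlogis(0.90)),
                         trans = stats::plogis),
                       meta_day_mean_by_cell = cell_values(
                         log(45),
                         c(d4 = log(55 / 45), d8 = log(65 / 45),
                           `salt:d8` = log(69 / 65)),
                         trans = exp),
                       meta_length_mean_by_cell = cell_values(
                         log(18.0),
                         c(inland = log(16.3 / 18.0), d4 = log(17.7 / 18.0),
                           d8 = log(17.2 / 18.0)),
                         trans = exp),
                       meta_length_sdlog = 0.05,
                       measurement_days = seq(0L, 49L, by = 7L),
                       seed = 1L) {
  cfg <- list(
    S0_true = S0_true,
    gamma_by_cell = complete_cell_map(gamma_by_cell, "gamma_by_cell"),
    alpha_by_cell = complete_cell_map(alpha_by_cell, "alpha_by_cell"),
    sigma_resid = sigma_resid,
    block_sd = block_sd,
    survival_prob_by_cell = complete_cell_map(survival_prob_by_cell,
                                              "survival_prob_by_cell"),
    meta_day_mean_by_cell = complete_cell_map(meta_day_mean_by_cell,
                                              "meta_day_mean_by_cell"),
    meta_length_mean_by_cell = complete_cell_map(meta_length_mean_by_cell,
                                                 "meta_length_mean_by_cell"),
    meta_length_sdlog = meta_length_sdlog,
    measurement_days = as.integer(measurement_days),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

# Accept either a full named map over the 12 cells or a single scalar
# recycled to all cells.
complete_cell_map <- function(x, what) {
  cells <- treatment_cells()$cell
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), length(cells)), cells))
  }
  if (is.null(names(x)) || !all(cells %in% names(x))) {
    stop(sprintf("%s must be a named vector covering all 12 cells", what),
         call. = FALSE)
  }
  x[cells]
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$S0_true) || cfg$S0_true <= 0) {
    fail("S0_true", "must be a positive length in mm")
  }
  if (any(cfg$gamma_by_cell <= 0)) fail("gamma_by_cell", "rates must be > 0")
  if (any(cfg$alpha_by_cell <= 0)) fail("alpha_by_cell", "rates must be > 0")
  if (cfg$sigma_resid < 0) fail("sigma_resid", "sd must be >= 0")
  if (cfg$block_sd < 0) fail("block_sd", "sd must be >= 0")
  p <- cfg$survival_prob_by_cell
  if (any(p < 0 | p > 1)) fail("survival_prob_by_cell", "must lie in [0, 1]")
  if (any(cfg$meta_day_mean_by_cell <= 0)) {
    fail("meta_day_mean_by_cell", "means must be > 0")
  }
  if (any(cfg$meta_length_mean_by_cell <= 0)) {
    fail("meta_length_mean_by_cell", "means must be > 0")
  }
  if (cfg$meta_length_sdlog < 0) fail("meta_length_sdlog", "sd must be >= 0")
  if (length(cfg$measurement_days) < 1L || any(cfg$measurement_days < 0)) {
    fail("measurement_days", "need at least one non-negative day")
  }
  if (is.na(cfg$seed)) fail("seed", "an integer seed is required")
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields override the defaults of [sim_config()]; the per-cell
#' maps may be given either as a scalar (recycled to all cells), as a full
#' named map over the 12 cell labels, or as an `intercept`/`effects` pair
#' interpreted by [cell_values()] on the field's link scale (log for
#' rates, means and days; logit for survival).
#'
#' @param path YAML file.
#' @param seed Seed overriding any value in the file (the command line
#'   requires one).
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  args <- list()
  link <- list(gamma_by_cell = exp, alpha_by_cell = exp,
               survival_prob_by_cell = stats::plogis,
               meta_day_mean_by_cell = exp, meta_length_mean_by_cell = exp)
  for (nm in names(raw)) {
    val <- raw[[nm]]
    if (nm %in% names(link) && is.list(val)) {
      args[[nm]] <- cell_values(val$intercept,
                                unlist(val$effects %||% list()),
                                trans = link[[nm]])
    } else if (grepl("_by_cell$", nm) && !is.null(names(unlist(val)))) {
      args[[nm]] <- unlist(val)
    } else {
      args[[nm]] <- val
    }
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
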