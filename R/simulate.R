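#' Simulate a synthetic rearing experiment
#'
#' Draws one complete dataset with the statistical structure the analysis
#' assumes:
#' \itemize{
#'   \item cup-mean total length follows the cell's Gompertz curve plus
#'     i.i.d. Gaussian noise (`sigma_resid`), recorded on the measurement
#'     grid while the container still holds at least one live, not yet
#'     metamorphosed individual;
#'   \item survival per unit is binomial with probability
#'     `plogis(qlogis(p_cell) + block effect)`;
#'   \item age at metamorphosis is Poisson per surviving individual with
#'     mean `exp(log(mean_cell) + block effect)`;
#'   \item length at metamorphosis is log-normal around the cell median
#'     with a block shift on the log scale;
#'   \item deaths are spread uniformly over the larval period.
#' }
#' Block effects are independent Gaussian draws per endpoint per block on
#' the respective link scale. The whole dataset is a deterministic
#' function of `config$seed`.
#'
#' @param design Units table from [build_design()].
#' @param config A [sim_config()].
#' @return A list of class `synthetic_dataset` with data frames `units`,
#'   `growth` (`unit_id`, `day`, `mean_total_length_mm`) and `metamorphs`
#'   (`unit_id`, `individual_id`, `survived`, `day_at_metamorphosis`,
#'   `total_length_mm`; the last two are `NA` for non-survivors), plus the
#'   `config` used.
#' @examples
#' ds <- simulate_dataset(build_design(), sim_config(seed = 42))
#' head(ds$growth)
#' @export
simulate_dataset <- function(design = build_design(), config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  units <- as_design_factors(as.data.frame(design))
  stopifnot(all(c("unit_id", "block", "n_initial") %in% names(units)))

  set.seed(config$seed)
  blocks <- sort(unique(units$block))
  b_eff <- list(
    surv = stats::setNames(stats::rnorm(length(blocks), 0, config$block_sd), blocks),
    day  = stats::setNames(stats::rnorm(length(blocks), 0, config$block_sd), blocks),
    len  = stats::setNames(stats::rnorm(length(blocks), 0, config$block_sd), blocks)
  )

  days <- config$measurement_days
  horizon <- max(days)
  growth_rows <- vector("list", nrow(units))
  meta_rows <- vector("list", nrow(units))

  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    bl <- as.character(u$block)
    n0 <- u$n_initial
    p <- stats::plogis(stats::qlogis(config$survival_prob_by_cell[[u$cell]]) +
                         b_eff$surv[[bl]])
    n_surv <- stats::rbinom(1L, n0, p)

    survived <- c(rep(TRUE, n_surv), rep(FALSE, n0 - n_surv))
    meta_day <- rep(NA_integer_, n0)
    meta_len <- rep(NA_real_, n0)
    if (n_surv > 0) {
      mu_day <- exp(log(config$meta_day_mean_by_cell[[u$cell]]) + b_eff$day[[bl]])
      meta_day[seq_len(n_surv)] <- stats::rpois(n_surv, mu_day)
      mu_loglen <- log(config$meta_length_mean_by_cell[[u$cell]]) + b_eff$len[[bl]]
      meta_len[seq_len(n_surv)] <-
        stats::rlnorm(n_surv, meanlog = mu_loglen, sdlog = config$meta_length_sdlog)
    }
    # death timing: uniform over the larval period (days 1..horizon)
    death_day <- rep(NA_integer_, n0)
    if (n_surv < n0) {
      death_day[(n_surv + 1L):n0] <-
        sample.int(max(horizon, 1L), n0 - n_surv, replace = TRUE)
    }

    present <- vapply(days, function(d) {
      sum(ifelse(survived, meta_day > d, death_day > d))
    }, numeric(1))
    keep <- present >= 1
    if (any(keep)) {
      mu <- gompertz_curve(days[keep], S0 = config$S0_true,
                           gamma = config$gamma_by_cell[[u$cell]],
                           alpha = config$alpha_by_cell[[u$cell]])
      obs <- mu + stats::rnorm(sum(keep), 0, config$sigma_resid)
      growth_rows[[i]] <- data.frame(unit_id = u$unit_id, day = days[keep],
                                     mean_total_length_mm = obs,
                                     stringsAsFactors = FALSE)
    }
    meta_rows[[i]] <- data.frame(
      unit_id = u$unit_id,
      individual_id = sprintf("%s-%02d", u$unit_id, seq_len(n0)),
      survived = survived,
      day_at_metamorphosis = meta_day,
      total_length_mm = meta_len,
      stringsAsFactors = FALSE
    )
  }

  out <- list(
    units = units[, c("unit_id", "block", "location", "salinity",
                      "density", "n_initial")],
    growth = do.call(rbind, growth_rows[!vapply(growth_rows, is.null, logical(1))]),
    metamorphs = do.call(rbind, meta_rows),
    config = config
  )
  rownames(out$growth) <- rownames(out$metamorphs) <- NULL
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic rearing experiment\n")
  cat(sprintf("  %d units, %d growth observations, %d individuals (%d survivors)\n",
              nrow(x$units), nrow(x$growth), nrow(x$metamorphs),
              sum(x$metamorphs$survived)))
  cat(sprintf("  measurement days: %s; seed %d\n",
              paste(x$config$measurement_days, collapse = ", "),
              x$config$seed))
  invisible(x)
}

#' Merge growth records with unit covariates
#'
#' @param dataset A `synthetic_dataset` or a list with `units` and
#'   `growth` data frames.
#' @return Data frame with one row per cup-mean observation and columns
#'   `unit_id`, `block`, `location`, `salinity`, `density`, `day`,
#'   `length`.
#' @export
growth_data <- function(dataset) {
  units <- as_design_factors(dataset$units)
  g <- merge(dataset$growth, units, by = "unit_id", sort = FALSE)
  out <- g[order(g$unit_id, g$day),
           c("unit_id", "block", "location", "salinity", "density", "day")]
  out$length <- g$mean_total_length_mm[order(g$unit_id, g$day)]
  rownames(out) <- NULL
  out
}

#' Merge metamorph records with unit covariates
#'
#' @inheritParams growth_data
#' @return Data frame with one row per individual.
#' @export
metamorph_data <- function(dataset) {
  units <- as_design_factors(dataset$units)
  m <- merge(dataset$metamorphs, units, by = "unit_id", sort = FALSE)
  m <- m[order(m$individual_id), ]
  rownames(m) <- NULL
  m
}
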