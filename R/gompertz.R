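#' Gompertz growth curve
#'
#' Expected total length at time `t` under the Gompertz model
#' \deqn{Y(t) = S_0 \exp\left[\frac{\gamma}{\alpha}(1 - e^{-\alpha t})\right],}
#' where `S0` is initial size (mm), `gamma` the maximum size-specific
#' growth rate (1/day) and `alpha` the exponential decay rate of that
#' growth rate (1/day): the curve solves dY/dt = gamma e^(-alpha t) Y.
#' It rises from `S0` at t = 0 to the asymptote `S0 exp(gamma/alpha)`.
#'
#' Evaluated through `expm1` so it is numerically stable as `alpha -> 0`,
#' where it tends to the exponential curve `S0 exp(gamma t)`.
#'
#' @param t Days since Gosner stage 25 (non-negative).
#' @param S0 Initial size, mm (> 0).
#' @param gamma Maximum size-specific growth rate, 1/day (> 0).
#' @param alpha Decay rate of the growth rate, 1/day (> 0).
#' @return Expected lengths, mm, same length as `t`.
#' @examples
#' gompertz_curve(c(0, 7, 14), S0 = 6, gamma = 0.12, alpha = 0.06)
#' @export
gompertz_curve <- function(t, S0, gamma, alpha) {
  stopifnot(S0 > 0, gamma > 0, alpha > 0)
  if (any(t < 0)) stop("negative time not allowed", call. = FALSE)
  S0 * exp(gamma * t * expm1_frac(alpha * t))
}

# (1 - exp(-x)) / x with the x -> 0 limit of 1; accurate for all x >= 0.
expm1_frac <- function(x) {
  out <- -expm1(-x) / x
  small <- x < 1e-12
  out[small] <- 1 - x[small] / 2
  out
}

# ---- model specification ---------------------------------------------------

.structure_labels <- c(
  "1"       = "1",
  "ADD"     = "Location + Salinity + Density",
  "LxS"     = "Location * Salinity + Density",
  "SxD"     = "Location + Salinity * Density",
  "FULL"    = "Location * Salinity * Density"
)

.structure_formulas <- list(
  "1"    = ~ 1,
  "ADD"  = ~ location + salinity + density,
  "LxS"  = ~ location * salinity + density,
  "SxD"  = ~ location + salinity * density,
  "FULL" = ~ location * salinity * density
)

match_structure <- function(x) {
  x <- as.character(x)
  if (x %in% names(.structure_labels)) return(x)
  hit <- names(.structure_labels)[match(x, .structure_labels)]
  if (is.na(hit)) {
    stop("unknown treatment structure: '", x, "' (use one of: ",
         paste(.structure_labels, collapse = "; "), ")", call. = FALSE)
  }
  hit
}

#' Define a Gompertz model parameterization
#'
#' A parameterization states which treatment structure shapes each of the
#' two growth parameters, gamma and alpha, out of the vocabulary `1`
#' (no effects), `Location + Salinity + Density`, `Location * Salinity +
#' Density`, `Location + Salinity * Density` and `Location * Salinity *
#' Density`. Initial size `S0` is always shared across treatments, as is
#' the residual sd. The short codes `"1"`, `"ADD"`, `"LxS"`, `"SxD"`,
#' `"FULL"` are accepted as synonyms.
#'
#' @param gamma,alpha Structure for each parameter (label or short code).
#' @return An object of class `gompertz_spec`.
#' @examples
#' gompertz_spec("ADD", "SxD")
#' @export
gompertz_spec <- function(gamma, alpha) {
  g <- match_structure(gamma)
  a <- match_structure(alpha)
  if (xor(g == "1", a == "1")) {
    stop("the no-effects structure '1' is only used in the single null ",
         "model where both gamma and alpha are '1'", call. = FALSE)
  }
  structure(list(gamma = g, alpha = a), class = "gompertz_spec")
}

#' @export
format.gompertz_spec <- function(x, ...) {
  sprintf("gamma: %s | alpha: %s",
          .structure_labels[[x$gamma]], .structure_labels[[x$alpha]])
}

#' @export
print.gompertz_spec <- function(x, ...) {
  cat("Gompertz parameterization (shared S0, shared sigma)\n  ",
      format(x), "\n", sep = "")
  invisible(x)
}

spec_label <- function(spec, which) .structure_labels[[spec[[which]]]]

#' Enumerate all 17 Gompertz parameterizations
#'
#' All 16 combinations of the four non-null treatment structures on gamma
#' and alpha, plus the single no-effects model (listed last). The order is
#' deterministic: gamma structure varying slowest in the order additive,
#' Location x Salinity, Salinity x Density, full interaction.
#'
#' @return List of 17 [gompertz_spec()] objects.
#' @examples
#' length(enumerate_model_specs())
#' @export
enumerate_model_specs <- function() {
  codes <- c("ADD", "LxS", "SxD", "FULL")
  specs <- list()
  for (g in codes) for (a in codes) {
    specs[[length(specs) + 1L]] <- gompertz_spec(g, a)
  }
  specs[[length(specs) + 1L]] <- gompertz_spec("1", "1")
  specs
}

#' Treatment design matrices for a parameterization
#'
#' Dummy (treatment) coding with reference levels coastal, fresh,
#' density 2; density is a 3-level factor contributing two columns as a
#' main effect. Column counts by structure: 1 -> 1, additive -> 5,
#' Location * Salinity + Density -> 6, Location + Salinity * Density -> 7,
#' full -> 12.
#'
#' @param spec A [gompertz_spec()].
#' @param units Units table carrying `location`, `salinity`, `density`.
#' @return List with matrices `gamma` and `alpha` (one row per unit).
#' @export
build_design_matrices <- function(spec, units) {
  units <- as_design_factors(as.data.frame(units))
  mm <- function(code) {
    stats::model.matrix(.structure_formulas[[code]], data = units)
  }
  list(gamma = mm(spec$gamma), alpha = mm(spec$alpha))
}

#' Number of estimated parameters of a parameterization
#'
#' Two shared parameters (S0 and the residual sd) plus the design-matrix
#' columns for gamma and for alpha.
#'
#' @param spec A [gompertz_spec()].
#' @return Integer parameter count (the `df` of the model table).
#' @examples
#' count_parameters(gompertz_spec("ADD", "SxD"))  # 14
#' @export
count_parameters <- function(spec) {
  ncols <- c("1" = 1L, "ADD" = 5L, "LxS" = 6L, "SxD" = 7L, "FULL" = 12L)
  2L + ncols[[spec$gamma]] + ncols[[spec$alpha]]
}

# ---- likelihood ------------------------------------------------------------

# Internal fit data: precomputed pieces shared by all likelihood
# evaluations for one (spec, data) pair.
gompertz_fit_data <- function(spec, data) {
  need <- c("unit_id", "location", "salinity", "density", "day", "length")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("growth data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("growth data is empty", call. = FALSE)
  units <- unique(data[, c("unit_id", "location", "salinity", "density")])
  units <- units[order(units$unit_id), ]
  X <- build_design_matrices(spec, units)
  idx <- match(data$unit_id, units$unit_id)
  list(y = as.numeric(data$length), t = as.numeric(data$day), idx = idx,
       Xg = X$gamma, Xa = X$alpha, n = nrow(data),
       p_g = ncol(X$gamma), p_a = ncol(X$alpha))
}

# theta = (log S0, beta_gamma, beta_alpha[, log sigma]); gamma and alpha get
# a log link so any coefficient vector yields positive rates.
unpack_theta <- function(theta, fd, with_sigma = FALSE) {
  p_g <- fd$p_g; p_a <- fd$p_a
  list(logS0 = theta[1L],
       bg = theta[1L + seq_len(p_g)],
       ba = theta[1L + p_g + seq_len(p_a)],
       logsigma = if (with_sigma) theta[2L + p_g + p_a] else NULL)
}

.big_nll <- 1e10  # optimizer-safe stand-in for an infinite penalty

gompertz_mu <- function(theta, fd) {
  th <- unpack_theta(theta, fd)
  g_u <- exp(drop(fd$Xg %*% th$bg))
  a_u <- exp(drop(fd$Xa %*% th$ba))
  if (any(!is.finite(g_u)) || any(!is.finite(a_u))) return(NULL)
  g <- g_u[fd$idx]; a <- a_u[fd$idx]
  mu <- exp(th$logS0) * exp(g * fd$t * expm1_frac(a * fd$t))
  if (any(!is.finite(mu))) return(NULL)
  list(mu = mu, g = g, a = a)
}

#' Negative log-likelihood of a Gompertz parameterization
#'
#' Gaussian likelihood of the observed cup-mean lengths around the
#' treatment-structured Gompertz curve: shared `S0` and residual sd,
#' per-unit gamma and alpha obtained from log-link linear predictors.
#' `theta` packs `(log S0, gamma coefficients, alpha coefficients,
#' log sigma)`. Returns a large finite penalty when the prediction
#' overflows, so optimizers can recover.
#'
#' @param theta Packed coefficient vector.
#' @param spec A [gompertz_spec()].
#' @param data Growth data as from [growth_data()].
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(theta, spec, data) {
  fd <- gompertz_fit_data(spec, data)
  if (length(theta) != 2L + fd$p_g + fd$p_a) {
    stop(sprintf("theta has length %d; spec needs %d (logS0, %d gamma, %d alpha, logsigma)",
                 length(theta), 2L + fd$p_g + fd$p_a, fd$p_g, fd$p_a),
         call. = FALSE)
  }
  sigma <- exp(theta[length(theta)])
  m <- gompertz_mu(theta[-length(theta)], fd)
  if (is.null(m)) return(.big_nll)
  -sum(stats::dnorm(fd$y, m$mu, sigma, log = TRUE))
}

# Profiled objective: sigma^2 replaced by RSS/n, so the optimizer works in
# (log S0, beta_gamma, beta_alpha) only. Same maximized likelihood.
nll_profiled <- function(theta, fd) {
  m <- gompertz_mu(theta, fd)
  if (is.null(m)) return(.big_nll)
  rss <- sum((fd$y - m$mu)^2)
  if (rss <= 0) rss <- 1e-300  # degenerate perfect fit
  fd$n / 2 * (log(2 * pi * rss / fd$n) + 1)
}

nll_profiled_grad <- function(theta, fd) {
  m <- gompertz_mu(theta, fd)
  if (is.null(m)) return(rep(0, length(theta)))
  r <- m$mu - fd$y
  rss <- sum(r^2)
  if (rss <= 0) return(rep(0, length(theta)))
  w <- (fd$n / rss) * r                     # d nll / d mu_i
  E <- exp(-m$a * fd$t)
  u <- m$g * fd$t * expm1_frac(m$a * fd$t)  # (g/a)(1 - e^{-at})
  d_logS0 <- sum(w * m$mu)
  wg <- w * m$mu * u                        # per-obs factor for gamma coefs
  wa <- w * m$mu * (m$g * fd$t * E - u)     # per-obs factor for alpha coefs
  d_bg <- drop(crossprod(fd$Xg[fd$idx, , drop = FALSE], wg))
  d_ba <- drop(crossprod(fd$Xa[fd$idx, , drop = FALSE], wa))
  unname(c(d_logS0, d_bg, d_ba))
}

# ---- fitting ---------------------------------------------------------------

#' Control parameters for Gompertz fitting
#'
#' @param n_restarts Number of optimizer starts (first from
#'   method-of-moments values, the rest jittered).
#' @param restart_sd Sd of the Gaussian jitter applied to the starting
#'   coefficients.
#' @param seed Seed for the restart jitter stream.
#' @param reltol Relative convergence tolerance passed to the optimizer.
#' @param maxit Iteration cap per start.
#' @param rate_bounds Admissible range for every per-unit gamma and alpha
#'   on the natural scale, 1/day; fits straying outside are penalized.
#' @return List of class `gompertz_control`.
#' @export
gompertz_control <- function(n_restarts = 10L, restart_sd = 0.3,
                             seed = 1014L, reltol = 1e-10, maxit = 500L,
                             rate_bounds = c(1e-4, 5)) {
  structure(list(n_restarts = as.integer(n_restarts), restart_sd = restart_sd,
                 seed = as.integer(seed), reltol = reltol,
                 maxit = as.integer(maxit), rate_bounds = rate_bounds),
            class = "gompertz_control")
}

# Method-of-moments starting values shared by every spec: S0 from the
# first-week mean, the asymptote from the last-week mean, alpha from the
# day at which the log-scale rise is half complete.
gompertz_start <- function(fd) {
  t0 <- min(fd$t); t1 <- max(fd$t)
  S0 <- max(mean(fd$y[fd$t == t0]), 0.5)
  A  <- max(mean(fd$y[fd$t == t1]), S0 * 1.05)
  ratio <- log(A / S0) * 1.1  # gamma/alpha; observed rise undershoots asymptote
  prog <- vapply(sort(unique(fd$t)), function(d) mean(fd$y[fd$t == d]), numeric(1))
  tt <- sort(unique(fd$t))
  half_val <- S0 * exp(log(A / S0) / 2)
  t_half <- tt[which.min(abs(prog - half_val))]
  alpha0 <- min(max(log(2) / max(t_half, 1), 0.005), 0.5)
  gamma0 <- alpha0 * ratio
  list(logS0 = log(S0), lg = log(gamma0), la = log(alpha0))
}

#' Fit one Gompertz parameterization by maximum likelihood
#'
#' Minimizes the (sigma-profiled) Gaussian negative log-likelihood by
#' multi-start BFGS with an analytic gradient, then reports the best
#' optimum. Per-unit gamma and alpha come from log-link linear predictors
#' over the unit's treatment cell; `S0` and the residual sd are shared.
#'
#' @param spec A [gompertz_spec()], or a structure label/short code pair
#'   via `gamma`/`alpha` arguments of [gompertz_spec()].
#' @param data Growth data as returned by [growth_data()]: one row per
#'   cup-mean observation with columns `unit_id`, `location`, `salinity`,
#'   `density`, `day`, `length`.
#' @param control A [gompertz_control()].
#' @return Object of class `gompertz_fit` with components `spec`,
#'   `coefficients` (named: `log_S0`, `gamma:*`, `alpha:*`, `log_sigma`),
#'   `logLik`, `k`, `n_obs`, `aicc`, `converged`, `n_restarts_used`,
#'   `cell_rates` (natural-scale fitted gamma and alpha per treatment
#'   cell) and the fitted data.
#' @examples
#' ds <- simulate_dataset(build_design(), sim_config(seed = 7))
#' fit <- fit_gompertz(gompertz_spec("ADD", "SxD"), growth_data(ds),
#'                     gompertz_control(n_restarts = 2))
#' coef(fit)[1:4]
#' @export
fit_gompertz <- function(spec, data, control = gompertz_control()) {
  stopifnot(inherits(spec, "gompertz_spec"))
  fd <- gompertz_fit_data(spec, data)
  k <- count_parameters(spec)
  if (fd$n < k + 1L) {
    stop(sprintf("under-determined fit: %d parameters need more than %d observations",
                 k, fd$n), call. = FALSE)
  }

  st <- gompertz_start(fd)
  base <- c(st$logS0,
            c(st$lg, rep(0, fd$p_g - 1L)),
            c(st$la, rep(0, fd$p_a - 1L)))

  # bound penalty: keep every per-unit rate inside rate_bounds
  lb <- log(control$rate_bounds[1L]); ub <- log(control$rate_bounds[2L])
  penalized <- function(theta) {
    th <- unpack_theta(theta, fd)
    lp_g <- drop(fd$Xg %*% th$bg); lp_a <- drop(fd$Xa %*% th$ba)
    pen <- sum(pmax(lp_g - ub, 0)^2 + pmax(lb - lp_g, 0)^2) +
           sum(pmax(lp_a - ub, 0)^2 + pmax(lb - lp_a, 0)^2)
    nll_profiled(theta, fd) + 1e4 * pen
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(control$seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  best <- NULL
  n_used <- 0L
  for (r in seq_len(control$n_restarts)) {
    start <- if (r == 1L) base else base + stats::rnorm(length(base), 0, control$restart_sd)
    opt <- try(stats::optim(start, fn = penalized, gr = function(th) nll_profiled_grad(th, fd),
                            method = "BFGS",
                            control = list(maxit = control$maxit,
                                           reltol = control$reltol)),
               silent = TRUE)
    n_used <- n_used + 1L
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
    # early exit: two starts agreeing on the optimum is strong evidence
    if (!is.null(best) && r >= 2L && abs(opt$value - best$value) < 1e-8) break
  }
  if (is.null(best)) {
    stop("all optimizer restarts failed for spec: ", format(spec), call. = FALSE)
  }

  theta <- best$par
  m <- gompertz_mu(theta, fd)
  rss <- sum((fd$y - m$mu)^2)
  sigma <- sqrt(max(rss / fd$n, 1e-300))
  ll <- -negative_log_likelihood(c(theta, log(sigma)), spec, data)

  coefs <- c(theta[1L],
             stats::setNames(theta[1L + seq_len(fd$p_g)],
                             paste0("gamma:", colnames(fd$Xg))),
             stats::setNames(theta[1L + fd$p_g + seq_len(fd$p_a)],
                             paste0("alpha:", colnames(fd$Xa))),
             log(sigma))
  names(coefs)[1L] <- "log_S0"
  names(coefs)[length(coefs)] <- "log_sigma"

  cells <- treatment_cells()
  Xc <- build_design_matrices(spec, cells)
  cell_rates <- data.frame(
    cell = cells$cell,
    gamma = exp(drop(Xc$gamma %*% theta[1L + seq_len(fd$p_g)])),
    alpha = exp(drop(Xc$alpha %*% theta[1L + fd$p_g + seq_len(fd$p_a)])),
    stringsAsFactors = FALSE
  )

  out <- list(
    spec = spec,
    coefficients = coefs,
    logLik = ll,
    k = k,
    n_obs = fd$n,
    aicc = aicc(ll, k, fd$n),
    converged = best$convergence == 0L,
    n_restarts_used = n_used,
    sigma = sigma,
    S0 = exp(theta[1L]),
    cell_rates = cell_rates,
    data = data
  )
  class(out) <- "gompertz_fit"
  out
}

#' @export
print.gompertz_fit <- function(x, digits = 4, ...) {
  cat("Gompertz growth fit (maximum likelihood)\n")
  cat("  ", format(x$spec), "\n", sep = "")
  cat(sprintf("  logLik %.3f | k = %d | n = %d | AICc %.2f | %s\n",
              x$logLik, x$k, x$n_obs, x$aicc,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  S0 = %.*g mm, sigma = %.*g mm\n",
              digits, x$S0, digits, x$sigma))
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) object$coefficients

#' @export
logLik.gompertz_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
predict.gompertz_fit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else newdata
  fd <- gompertz_fit_data(object$spec, data)
  theta <- object$coefficients[-length(object$coefficients)]
  unname(gompertz_mu(unname(theta), fd)$mu)
}

#' @export
fitted.gompertz_fit <- function(object, ...) predict(object)

#' @export
residuals.gompertz_fit <- function(object, ...) {
  object$data$length - fitted(object)
}

#' @export
summary.gompertz_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.gompertz_fit")
}

#' @export
print.summary.gompertz_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFitted natural-scale rates per treatment cell:\n")
  print(transform(x$fit$cell_rates,
                  gamma = signif(gamma, 4), alpha = signif(alpha, 4)),
        row.names = FALSE)
  cat("\nCoefficients (log scale):\n")
  print(signif(x$fit$coefficients, 4))
  invisible(x)
}

# ---- information criteria --------------------------------------------------

#' Small-sample-corrected Akaike information criterion
#'
#' AICc = -2 log L + 2k + 2k(k + 1) / (n - k - 1).
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations; must exceed k + 1.
#' @return Scalar AICc.
#' @examples
#' aicc(-10, 4, 20)  # 30.667
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: need n > k + 1 (got n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc differences
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)`: the relative
#' likelihood of each model given the candidate set, order-preserving.
#'
#' @param delta_aicc Non-negative AICc differences with minimum 0.
#' @return Probabilities summing to 1, same order as the input.
#' @examples
#' akaike_weights(c(0, 2, 4))
#' @export
akaike_weights <- function(delta_aicc) {
  if (length(delta_aicc) == 0L) stop("empty candidate set", call. = FALSE)
  if (any(delta_aicc < 0) || min(delta_aicc) > 1e-8) {
    stop("delta_aicc must be non-negative with minimum 0", call. = FALSE)
  }
  rel <- exp(-delta_aicc / 2)
  rel / sum(rel)
}
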