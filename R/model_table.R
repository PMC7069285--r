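#' Fit all 17 parameterizations and rank them by AICc
#'
#' Fits every model from [enumerate_model_specs()] to the same growth
#' data, ranks by ascending AICc (ties broken by enumeration order) and
#' attaches AICc differences and Akaike weights. Non-convergent fits are
#' kept and flagged, never dropped.
#'
#' @param data Growth data as returned by [growth_data()].
#' @param control A [gompertz_control()] shared by all fits.
#' @param specs Candidate list (default all 17).
#' @return Object of class `gompertz_modsel`: a list with `table` (one
#'   row per model: `rank`, `gamma_formula`, `alpha_formula`, `logLik`,
#'   `k`, `n`, `AICc`, `dAICc`, `weight`, `converged`) and `fits` (the
#'   [fit_gompertz()] objects in table order).
#' @examples
#' \donttest{
#' ds <- simulate_dataset(build_design(), sim_config(seed = 3))
#' sel <- gompertz_select(growth_data(ds), gompertz_control(n_restarts = 2))
#' head(sel$table, 3)
#' }
#' @export
gompertz_select <- function(data, control = gompertz_control(),
                            specs = enumerate_model_specs()) {
  fits <- lapply(specs, function(sp) fit_gompertz(sp, data, control))
  tab <- data.frame(
    gamma_formula = vapply(specs, spec_label, "", which = "gamma"),
    alpha_formula = vapply(specs, spec_label, "", which = "alpha"),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    k = vapply(fits, function(f) f$k, integer(1)),
    n = vapply(fits, function(f) f$n_obs, integer(1)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$AICc, seq_len(nrow(tab)))  # enumeration order breaks ties
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$rank <- seq_len(nrow(tab))
  tab$dAICc <- tab$AICc - tab$AICc[1L]
  tab$weight <- akaike_weights(tab$dAICc)
  tab <- tab[, c("rank", "gamma_formula", "alpha_formula", "logLik", "k",
                 "n", "AICc", "dAICc", "weight", "converged")]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "gompertz_modsel")
}

#' @rdname gompertz_select
#' @export
build_model_table <- gompertz_select

#' @export
print.gompertz_modsel <- function(x, n = 17L, ...) {
  cat("Gompertz model comparison (AICc), ", nrow(x$table), " parameterizations\n\n",
      sep = "")
  tab <- utils::head(x$table, n)
  show <- data.frame(
    rank = tab$rank, gamma = tab$gamma_formula, alpha = tab$alpha_formula,
    df = tab$k, dAICc = round(tab$dAICc, 1),
    weight = ifelse(tab$weight < 0.001, "<0.001",
                    formatC(tab$weight, format = "f", digits = 3)),
    stringsAsFactors = FALSE
  )
  if (any(!tab$converged)) {
    show$note <- ifelse(tab$converged, "", "not converged")
  }
  print(show, row.names = FALSE)
  invisible(x)
}

#' Best-supported model of a comparison
#'
#' @param x A `gompertz_modsel`.
#' @return The rank-1 [fit_gompertz()] object.
#' @export
best_fit <- function(x) {
  stopifnot(inherits(x, "gompertz_modsel"))
  x$fits[[1L]]
}
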