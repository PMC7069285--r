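#' Write a dataset to the three experiment CSVs
#'
#' Writes `units.csv` (`unit_id`, `block`, `location`, `salinity`,
#' `density`, `n_initial`), `growth.csv` (`unit_id`, `day`,
#' `mean_total_length_mm`) and `metamorphs.csv` (`unit_id`,
#' `individual_id`, `survived`, `day_at_metamorphosis`,
#' `total_length_mm`). Missing endpoint fields for non-survivors are
#' written as empty strings; UTF-8, header row, `.` decimal separator.
#'
#' @param dataset A `synthetic_dataset` (or compatible list).
#' @param dir Output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) {
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, na = "",
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  units <- dataset$units
  units$location <- as.character(units$location)
  units$salinity <- as.character(units$salinity)
  units$density <- as.character(units$density)
  wr(units[, c("unit_id", "block", "location", "salinity", "density",
               "n_initial")], "units.csv")
  g <- dataset$growth
  g$mean_total_length_mm <- formatC(g$mean_total_length_mm, format = "g",
                                    digits = 10)
  wr(g, "growth.csv")
  m <- dataset$metamorphs
  m$total_length_mm <- ifelse(is.na(m$total_length_mm), NA,
                              formatC(m$total_length_mm, format = "g",
                                      digits = 10))
  wr(m, "metamorphs.csv")
  invisible(dir)
}

read_checked_csv <- function(path, cols) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(names(cols), names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(cols)) {
    conv <- switch(cols[[nm]], integer = as.integer, numeric = as.numeric,
                   logical = as.logical, character = as.character)
    raw <- df[[nm]]
    was_na <- is.na(raw) | (is.character(raw) & raw == "")
    val <- suppressWarnings(conv(raw))
    bad <- which(is.na(val) & !was_na)
    if (length(bad)) {
      stop(sprintf("%s: row %d, column '%s': cannot parse '%s' as %s",
                   basename(path), bad[1L], nm, raw[bad[1L]], cols[[nm]]),
           call. = FALSE)
    }
    df[[nm]] <- val
  }
  df
}

#' Read a dataset from the three experiment CSVs
#'
#' Validates schemas (file, row and column named in every error), the
#' allowed factor levels (densities 2/4/8, blocks 1-6) and referential
#' integrity: every growth and metamorph record must point to a unit in
#' `units.csv`.
#'
#' @param dir Directory holding `units.csv`, `growth.csv`,
#'   `metamorphs.csv`.
#' @return A list of class `synthetic_dataset` (without a `config`).
#' @export
read_dataset <- function(dir) {
  units <- read_checked_csv(file.path(dir, "units.csv"),
    c(unit_id = "character", block = "integer", location = "character",
      salinity = "character", density = "character", n_initial = "integer"))
  units <- tryCatch(as_design_factors(units), error = function(e) {
    stop("units.csv: ", conditionMessage(e), call. = FALSE)
  })
  units$cell <- NULL
  if (anyDuplicated(units$unit_id)) {
    stop("units.csv: duplicated unit_id", call. = FALSE)
  }
  if (any(units$n_initial != as.integer(as.character(units$density)))) {
    stop("units.csv: n_initial must equal the density level", call. = FALSE)
  }
  growth <- read_checked_csv(file.path(dir, "growth.csv"),
    c(unit_id = "character", day = "integer", mean_total_length_mm = "numeric"))
  orphan <- which(!growth$unit_id %in% units$unit_id)
  if (length(orphan)) {
    stop(sprintf("growth.csv: row %d references unknown unit_id '%s'",
                 orphan[1L], growth$unit_id[orphan[1L]]), call. = FALSE)
  }
  meta <- read_checked_csv(file.path(dir, "metamorphs.csv"),
    c(unit_id = "character", individual_id = "character", survived = "logical",
      day_at_metamorphosis = "integer", total_length_mm = "numeric"))
  orphan <- which(!meta$unit_id %in% units$unit_id)
  if (length(orphan)) {
    stop(sprintf("metamorphs.csv: row %d references unknown unit_id '%s'",
                 orphan[1L], meta$unit_id[orphan[1L]]), call. = FALSE)
  }
  counts <- table(factor(meta$unit_id, levels = units$unit_id))
  if (any(counts != units$n_initial)) {
    bad <- names(counts)[which(counts != units$n_initial)[1L]]
    stop(sprintf("metamorphs.csv: unit '%s' has %d records but n_initial %d",
                 bad, counts[[bad]],
                 units$n_initial[units$unit_id == bad]), call. = FALSE)
  }
  structure(list(units = units, growth = growth, metamorphs = meta),
            class = "synthetic_dataset")
}

#' Write the ranked model table to CSV
#'
#' @param modsel A [gompertz_select()] result.
#' @param path Output CSV.
#' @export
write_model_table <- function(modsel, path) {
  tab <- modsel$table
  tab$logLik <- formatC(tab$logLik, format = "g", digits = 10)
  tab$AICc <- formatC(tab$AICc, format = "g", digits = 10)
  tab$dAICc <- formatC(tab$dAICc, format = "g", digits = 10)
  tab$weight <- formatC(tab$weight, format = "g", digits = 10)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write full coefficient vectors of all fits to JSON
#'
#' @param modsel A [gompertz_select()] result.
#' @param path Output JSON.
#' @export
write_fits_json <- function(modsel, path) {
  fits <- lapply(modsel$fits, function(f) {
    list(gamma_formula = spec_label(f$spec, "gamma"),
         alpha_formula = spec_label(f$spec, "alpha"),
         coefficients = as.list(f$coefficients),
         logLik = f$logLik, k = f$k, n = f$n_obs, aicc = f$aicc,
         converged = f$converged, n_restarts_used = f$n_restarts_used)
  })
  jsonlite::write_json(fits, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

endpoint_report_list <- function(report) {
  lapply(report$endpoints, function(ep) {
    if (!is.null(ep$error)) return(list(error = ep$error))
    tr <- ep$trace
    list(
      family = tr$family,
      three_way_retained = tr$three_way_retained,
      dropped = tr$steps,
      final_terms = tr$final_spec$fixed_terms,
      sigma_block = tr$final_fit$sigma_b,
      main_effects = tr$main_effects,
      cell_means = ep$cell_means,
      dispersion = if (is.na(ep$dispersion)) NULL else ep$dispersion
    )
  })
}

#' Write the endpoint report to JSON
#'
#' @param report An [analyze_endpoints()] result.
#' @param path Output JSON.
#' @export
write_endpoint_report <- function(report, path) {
  jsonlite::write_json(endpoint_report_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
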