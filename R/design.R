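#' Factor levels for the experimental design
#'
#' The experiment crosses two source populations (coastal, salt-exposed;
#' inland, salt-naive), two rearing salinities (fresh water; 4 ppt salt
#' water) and three larval densities (2, 4 or 8 tadpoles per container).
#' Density is treated throughout as an ordered 3-level factor, never as a
#' continuous covariate. Reference levels are coastal, fresh, density 2.
#'
#' @keywords internal
#' @name design-levels
NULL

.location_levels <- c("coastal", "inland")
.salinity_levels <- c("fresh", "salt4ppt")
.density_levels  <- c("2", "4", "8")
.n_blocks        <- 6L

#' Enumerate the 12 treatment cells
#'
#' @return A data frame with 12 rows and factor columns `location`,
#'   `salinity`, `density` (density is an ordered factor with levels
#'   2 < 4 < 8, stored unordered for treatment contrasts), plus a `cell`
#'   label of the form `coastal.fresh.2`.
#' @examples
#' treatment_cells()
#' @export
treatment_cells <- function() {
  cells <- expand.grid(
    density  = factor(.density_levels, levels = .density_levels),
    salinity = factor(.salinity_levels, levels = .salinity_levels),
    location = factor(.location_levels, levels = .location_levels),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("location", "salinity", "density")]
  cells$cell <- cell_label(cells)
  cells
}

cell_label <- function(d) {
  paste(as.character(d$location), as.character(d$salinity),
        as.character(d$density), sep = ".")
}

#' Build the full factorial rearing design
#'
#' Returns the balanced design of the experiment: 3 densities x 2
#' salinities x 2 locations arranged in 6 replicate spatial blocks, i.e.
#' 72 experimental units (rearing containers). Each (cell, block)
#' combination occurs exactly once. `n_initial` equals the density level:
#' it is the number of tadpoles placed in the container.
#'
#' Unit ids are stable: block-major, then location, salinity, density.
#'
#' @param n_blocks Number of replicate spatial blocks (default 6).
#' @return A data frame of class `c("experiment_design", "data.frame")`
#'   with columns `unit_id`, `block`, `location`, `salinity`, `density`,
#'   `n_initial`.
#' @examples
#' d <- build_design()
#' nrow(d)            # 72
#' table(d$density)   # 24 units per density level
#' @export
build_design <- function(n_blocks = .n_blocks) {
  stopifnot(is.numeric(n_blocks), length(n_blocks) == 1L, n_blocks >= 1)
  n_blocks <- as.integer(n_blocks)
  cells <- treatment_cells()
  design <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    data.frame(block = b, cells, stringsAsFactors = FALSE)
  }))
  design$n_initial <- as.integer(as.character(design$density))
  design$unit_id <- sprintf("U%02d", seq_len(nrow(design)))
  design$block <- as.integer(design$block)
  design <- design[, c("unit_id", "block", "location", "salinity",
                       "density", "n_initial", "cell")]
  rownames(design) <- NULL
  class(design) <- c("experiment_design", "data.frame")
  design
}

# Ensure the treatment columns of a units table carry the canonical factor
# levels; errors on unknown levels.
as_design_factors <- function(units) {
  chk <- function(x, levels, what) {
    x <- as.character(x)
    bad <- !x %in% levels
    if (any(bad)) {
      stop(sprintf("unknown %s level(s): %s (allowed: %s)", what,
                   paste(unique(x[bad]), collapse = ", "),
                   paste(levels, collapse = ", ")), call. = FALSE)
    }
    factor(x, levels = levels)
  }
  units$location <- chk(units$location, .location_levels, "location")
  units$salinity <- chk(units$salinity, .salinity_levels, "salinity")
  units$density  <- chk(units$density,  .density_levels,  "density")
  units$cell <- cell_label(units)
  units
}
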