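#' Specify a balanced shelf-life storage design
#'
#' Describes the full factorial storage experiment: sampling times (days),
#' storage temperatures (deg C, each temperature implying its light regime),
#' packaging materials, and the number of replicate vials per cell.
#'
#' The default levels reproduce the reference experiment: nine sampling times
#' over 270 days, storage at 10 deg C (dark) and 25 deg C (diffused light),
#' and four vial materials - polypropylene (PP), clear glass (CG), amber
#' glass (AG) and amber glass wrapped in aluminium foil (AGA) - with two
#' replicate vials per condition.
#'
#' @param time_levels numeric vector of storage times in days.
#' @param temperature_levels numeric vector of storage temperatures in deg C.
#' @param material_levels character vector of packaging material codes.
#' @param n_replicates replicate vials per factor-level combination.
#' @return an object of class `design_spec`.
#' @seealso [generate_design()]
#' @export
#' @examples
#' spec <- design_spec()
#' nrow(generate_design(spec)) # 9 * 2 * 4 * 2 = 144
design_spec <- function(time_levels = c(15, 30, 45, 60, 90, 120, 150, 190, 270),
                        temperature_levels = c(10, 25),
                        material_levels = c("PP", "CG", "AG", "AGA"),
                        n_replicates = 2) {
  check_levels <- function(x, what, numeric = TRUE) {
    if (length(x) == 0L) stop("`", what, "` must be non-empty", call. = FALSE)
    if (anyDuplicated(x)) stop("`", what, "` must be duplicate-free", call. = FALSE)
    if (numeric && (!is.numeric(x) || anyNA(x))) {
      stop("`", what, "` must be numeric without NA", call. = FALSE)
    }
  }
  check_levels(time_levels, "time_levels")
  check_levels(temperature_levels, "temperature_levels")
  check_levels(material_levels, "material_levels", numeric = FALSE)
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("`n_replicates` must be a single integer >= 1", call. = FALSE)
  }
  structure(
    list(
      time_levels = as.numeric(time_levels),
      temperature_levels = as.numeric(temperature_levels),
      material_levels = as.character(material_levels),
      n_replicates = as.integer(n_replicates)
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Shelf-life design spec\n")
  cat("  times (days):     ", paste(x$time_levels, collapse = ", "), "\n")
  cat("  temperatures (C): ", paste(x$temperature_levels, collapse = ", "), "\n")
  cat("  materials:        ", paste(x$material_levels, collapse = ", "), "\n")
  cat("  replicates/cell:  ", x$n_replicates, "\n")
  invisible(x)
}

#' Generate the design table of a balanced factorial experiment
#'
#' Expands a [design_spec()] into one row per measurement: the complete
#' crossing of time, temperature and material, with `n_replicates` rows per
#' cell. The expansion is deterministic, so the same spec always yields the
#' same table (row ids included).
#'
#' @param spec a [design_spec()].
#' @return a `data.frame` with columns `row_id`, `time`, `temperature`,
#'   `material` (factor, levels in the order given) and `replicate`.
#' @export
generate_design <- function(spec) {
  if (!inherits(spec, "design_spec")) {
    stop("`spec` must be a design_spec object", call. = FALSE)
  }
  grid <- expand.grid(
    replicate = seq_len(spec$n_replicates),
    material = factor(spec$material_levels, levels = spec$material_levels),
    temperature = spec$temperature_levels,
    time = spec$time_levels,
    KEEP.OUT.ATTRS = FALSE
  )
  design <- data.frame(
    row_id = sprintf("S%03d", seq_len(nrow(grid))),
    time = grid$time,
    temperature = grid$temperature,
    material = grid$material,
    replicate = as.integer(grid$replicate),
    stringsAsFactors = FALSE
  )
  design
}

# TRUE iff the three-factor crossing is complete with equal cell counts.
design_is_balanced <- function(design) {
  tab <- table(design$time, design$temperature, design$material)
  all(tab == tab[1L]) && tab[1L] >= 1L
}
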