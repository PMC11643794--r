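#' Remove saturated spectral channels
#'
#' Drops every channel whose mean absorbance over all spectra exceeds
#' `threshold` (default 2.5 AU, the linearity limit of a transmission
#' measurement at long optical path). Masking is computed on the mean
#' spectrum so that all rows keep a common wavenumber grid; rows are never
#' removed. Applying the mask twice is a no-op.
#'
#' @param spectra numeric matrix with wavenumber column names.
#' @param threshold absorbance threshold, AU (> 0).
#' @return the matrix restricted to retained channels, with attribute
#'   `masked_wavenumbers` listing what was dropped.
#' @export
mask_saturated <- function(spectra, threshold = 2.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  spectra <- as.matrix(spectra)
  wn <- wavenumbers(spectra)
  keep <- colMeans(spectra) <= threshold
  if (!any(keep)) {
    stop("all channels exceed the saturation threshold; nothing retained",
         call. = FALSE)
  }
  out <- spectra[, keep, drop = FALSE]
  attr(out, "masked_wavenumbers") <- wn[!keep]
  out
}

#' Per-spectrum linear baseline correction
#'
#' Fits a first-degree polynomial in wavenumber to each spectrum by least
#' squares and subtracts it, removing the offset and tilt that residual
#' turbidity adds to a transmission spectrum. Every output row has zero mean
#' and zero linear trend; adding any straight line to an input row leaves
#' its output unchanged.
#'
#' @param spectra numeric matrix with wavenumber column names (>= 2 channels).
#' @return the detrended matrix.
#' @export
baseline_correct <- function(spectra) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) < 2L) {
    stop("baseline correction needs at least 2 channels", call. = FALSE)
  }
  wn <- wavenumbers(spectra)
  basis <- cbind(1, wn - mean(wn))
  # projection of each row onto the straight-line space, removed at once
  coefs <- spectra %*% basis %*% solve(crossprod(basis))
  out <- spectra - coefs %*% t(basis)
  attr(out, "masked_wavenumbers") <- attr(spectra, "masked_wavenumbers")
  out
}

#' Mean-center spectra and package the analysis matrix
#'
#' Subtracts the grand-mean spectrum (stored as `grand_mean`) from every
#' row. Centering is idempotent and exactly invertible: adding `grand_mean`
#' back to `matrix` reproduces the input.
#'
#' @param spectra numeric matrix with wavenumber column names (>= 1 row).
#' @param provenance character vector of the steps already applied.
#' @return an object of class `preprocessed_spectra`: a list with `matrix`
#'   (centered), `wavenumbers`, `grand_mean` and `provenance`.
#' @export
mean_center <- function(spectra, provenance = character()) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 1L) stop("need at least one spectrum", call. = FALSE)
  mu <- colMeans(spectra)
  centered <- sweep(spectra, 2, mu)
  structure(
    list(matrix = centered,
         wavenumbers = wavenumbers(spectra),
         grand_mean = mu,
         provenance = c(provenance, "mean_center")),
    class = "preprocessed_spectra"
  )
}

#' Full preprocessing pipeline: mask, baseline-correct, center
#'
#' Applies the fixed preprocessing order used throughout the package:
#' saturation masking, per-spectrum linear baseline correction, then mean
#' centering. The order is recorded in the result's `provenance`.
#'
#' @param spectra raw spectra matrix.
#' @param threshold saturation threshold in AU for [mask_saturated()].
#' @return a `preprocessed_spectra` object.
#' @export
#' @examples
#' sim <- simulate_shelf_life(seed = 1)
#' prep <- preprocess_spectra(sim$spectra)
#' prep
preprocess_spectra <- function(spectra, threshold = 2.5) {
  masked <- mask_saturated(spectra, threshold = threshold)
  corrected <- baseline_correct(masked)
  out <- mean_center(corrected,
                     provenance = c("mask_saturated", "baseline_correct"))
  out$masked_wavenumbers <- attr(masked, "masked_wavenumbers")
  out
}

#' @export
print.preprocessed_spectra <- function(x, ...) {
  cat("Preprocessed spectra:", nrow(x$matrix), "spectra x",
      ncol(x$matrix), "channels\n")
  cat("  wavenumbers:", min(x$wavenumbers), "-", max(x$wavenumbers), "cm^-1\n")
  cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  if (!is.null(x$masked_wavenumbers) && length(x$masked_wavenumbers)) {
    cat("  masked channels:", length(x$masked_wavenumbers), "\n")
  }
  invisible(x)
}
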