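#' NIR spectral basis for the forward model
#'
#' Defines the Gaussian-band basis used to synthesize NIR-like oil spectra.
#' The default bands sit at the main absorptions of a polyunsaturated
#' vegetable oil in the 4000-9000 cm^-1 region: C-H/C=C stretching
#' combinations (4602-4700 cm^-1), the C=O second overtone (5180 cm^-1), a
#' bound-water combination (5269 cm^-1), first overtones of methylenic and
#' methylic C-H stretches (5678-5963 cm^-1), C-H combination bands
#' (7070-7260 cm^-1), second overtones (8260-8395 cm^-1) and a carbonyl band
#' (8580 cm^-1), plus a broad combination band near 4200 cm^-1 that -
#' together with the 5790 cm^-1 methylenic band - drives the detector into
#' saturation at a 4 mm optical path.
#'
#' Band amplitudes respond linearly to the sample's oxidation state, encoded
#' as the standardized (PV, K268) pair: `band_sensitivities` is an
#' `n_bands x 2` matrix (columns `pv`, `k268`) of absorbance change per
#' standard deviation of each marker. Unsaturation bands lose intensity as
#' double bonds are consumed (negative coefficients); carbonyl-related bands
#' gain (positive).
#'
#' @param band_centers band positions, cm^-1.
#' @param band_widths Gaussian standard deviations, cm^-1 (> 0).
#' @param band_base_amplitudes absorbance at the unoxidized mean state, AU.
#' @param band_sensitivities `n_bands x 2` matrix, columns `pv` and `k268`.
#' @param saturation_regions 2-column matrix of wavenumber intervals
#'   (inclusive) where the detector saturates.
#' @param grid instrument wavenumber grid, cm^-1.
#' @param sat_level absorbance floor applied inside saturation regions, AU.
#' @return an object of class `spectral_basis`.
#' @export
spectral_basis <- function(band_centers = NULL,
                           band_widths = NULL,
                           band_base_amplitudes = NULL,
                           band_sensitivities = NULL,
                           saturation_regions = rbind(c(4000, 4440), c(5770, 5875)),
                           grid = seq(4000, 9000, by = 8),
                           sat_level = 2.8) {
  default <- data.frame(
    center = c(4200, 4602, 4667, 4700, 5180, 5269, 5678, 5790,
               5892, 5963, 7070, 7190, 7260, 8260, 8395, 8580),
    width  = c(160, 30, 30, 32, 45, 40, 45, 30,
               35, 30, 45, 45, 40, 55, 55, 60),
    amp    = c(3.2, 0.9, 1.0, 0.8, 0.6, 0.35, 1.4, 2.9,
               1.1, 0.7, 0.45, 0.5, 0.35, 0.25, 0.22, 0.12),
    s_pv   = c(0, -0.030, -0.035, 0.020, 0.015, 0.010, 0.050, 0,
               -0.045, -0.020, 0.012, -0.015, 0.008, 0.010, -0.008, 0.006),
    s_k268 = c(0, -0.010, -0.012, 0.030, 0.040, 0.015, 0.010, 0,
               -0.015, -0.010, 0.004, -0.005, 0.003, 0.004, -0.003, 0.010)
  )
  centers <- band_centers %||% default$center
  widths <- band_widths %||% default$width
  amps <- band_base_amplitudes %||% default$amp
  sens <- band_sensitivities %||%
    cbind(pv = default$s_pv, k268 = default$s_k268)
  sens <- as.matrix(sens)
  if (is.null(colnames(sens))) colnames(sens) <- c("pv", "k268")
  nb <- length(centers)
  if (length(widths) != nb || length(amps) != nb || nrow(sens) != nb) {
    stop("band fields must all have one entry per band", call. = FALSE)
  }
  if (any(widths <= 0)) stop("band widths must be > 0", call. = FALSE)
  if (any(centers < min(grid)) || any(centers > max(grid))) {
    stop("band centers must lie within the instrument grid", call. = FALSE)
  }
  saturation_regions <- matrix(as.numeric(saturation_regions), ncol = 2)
  structure(
    list(band_centers = as.numeric(centers),
         band_widths = as.numeric(widths),
         band_base_amplitudes = as.numeric(amps),
         band_sensitivities = sens,
         saturation_regions = saturation_regions,
         grid = as.numeric(grid),
         sat_level = sat_level),
    class = "spectral_basis"
  )
}

# Standardize a chemistry marker; a zero-variance marker maps to all zeros.
standardize_marker <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate NIR-like spectra from oxidation chemistry
#'
#' Forward model for the instrument: each spectrum is a per-sample linear
#' baseline (random offset and tilt emulating turbidity), plus Gaussian
#' bands whose amplitudes respond linearly to the sample's oxidation state
#' (the standardized PV and K268 values), plus iid Gaussian channel noise.
#' Channels inside the basis's saturation regions are then floored at
#' `basis$sat_level`, emulating a saturated detector whose reported
#' absorbance exceeds the 2.5 AU linearity limit. Deterministic given
#' `seed`.
#'
#' @param chem chemistry table from [simulate_chemistry()].
#' @param basis a [spectral_basis()].
#' @param seed integer RNG seed.
#' @param noise_sd iid channel noise sd, AU.
#' @param baseline_offset_sd sd of the per-spectrum baseline offset, AU.
#' @param baseline_slope_sd sd of the per-spectrum baseline tilt, AU per cm^-1.
#' @return numeric matrix (rows = samples named by `row_id`, columns named by
#'   wavenumber).
#' @export
#' @examples
#' design <- generate_design(design_spec())
#' chem <- simulate_chemistry(design, seed = 1)
#' spectra <- simulate_spectra(chem, seed = 2)
#' dim(spectra)
simulate_spectra <- function(chem, basis = spectral_basis(), seed = 1,
                             noise_sd = 0.002,
                             baseline_offset_sd = 0.02,
                             baseline_slope_sd = 2e-6) {
  if (!inherits(basis, "spectral_basis")) {
    stop("`basis` must be a spectral_basis object", call. = FALSE)
  }
  n <- nrow(chem)
  grid <- basis$grid
  p <- length(grid)
  state <- cbind(pv = standardize_marker(chem$pv),
                 k268 = standardize_marker(chem$k268))
  # n x n_bands amplitude matrix: base + sensitivity * oxidation state
  amp <- matrix(basis$band_base_amplitudes, n, length(basis$band_centers),
                byrow = TRUE) +
    state %*% t(basis$band_sensitivities)
  # p x n_bands Gaussian profiles
  profiles <- exp(-outer(grid, basis$band_centers, "-")^2 /
                    rep(2 * basis$band_widths^2, each = p))
  x <- amp %*% t(profiles)
  rnd <- with_seed(seed, {
    list(offset = rnorm(n, sd = baseline_offset_sd),
         slope = rnorm(n, sd = baseline_slope_sd),
         noise = matrix(rnorm(n * p, sd = noise_sd), n, p))
  })
  x <- x + outer(rnd$offset, rep(1, p)) +
    outer(rnd$slope, grid - mean(grid)) + rnd$noise
  for (k in seq_len(nrow(basis$saturation_regions))) {
    lo <- basis$saturation_regions[k, 1]
    hi <- basis$saturation_regions[k, 2]
    idx <- which(grid >= lo & grid <= hi)
    if (length(idx)) x[, idx] <- pmax(x[, idx], basis$sat_level)
  }
  dimnames(x) <- list(chem$row_id, format(grid, trim = TRUE, scientific = FALSE))
  x
}

#' Simulate a complete shelf-life dataset
#'
#' Convenience wrapper tying the three generator stages together: design
#' table, oxidation-chemistry trajectories, and NIR-like spectra. The three
#' stages draw from independent seeds derived from `seed`.
#'
#' @param spec a [design_spec()].
#' @param params an [oxidation_params()].
#' @param basis a [spectral_basis()].
#' @param seed integer master seed.
#' @param ... further arguments passed to [simulate_spectra()].
#' @return list with elements `design`, `chemistry`, `spectra`.
#' @export
simulate_shelf_life <- function(spec = design_spec(),
                                params = oxidation_params(),
                                basis = spectral_basis(),
                                seed = 1, ...) {
  design <- generate_design(spec)
  chem <- simulate_chemistry(design, params, seed = seed)
  spectra <- simulate_spectra(chem, basis, seed = seed + 1e6, ...)
  list(design = design, chemistry = chem, spectra = spectra)
}
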