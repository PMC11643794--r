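#' Oxidation kinetics parameters
#'
#' Parameters of the forward model for oil-oxidation chemistry over storage.
#' The peroxide value (PV) follows rise-then-decay kinetics:
#' \deqn{pv(t) = pv_0 + A \, r \, (1 - e^{-g r t}) \, e^{-d r t}}
#' where \eqn{r} is the product of the temperature and material rate
#' multipliers, \eqn{g} the primary-oxidation growth rate and \eqn{d} the
#' peroxide-decomposition rate. Conjugated dienes (K232) co-move with PV;
#' conjugated trienes (K268) accumulate monotonically as secondary oxidation
#' products: \eqn{k268(t) = k268_0 + c \, r \, (1 - e^{-g r t})}.
#'
#' Default rate multipliers encode the physics of the storage conditions:
#' higher temperature accelerates the radical chain reaction
#' (`temp_factor[25] > temp_factor[10]`), and materials order by combined
#' oxygen permeability and light transmittance - polypropylene (PP, oxygen
#' permeable) worst, then clear glass (CG), amber glass (AG), and amber glass
#' with aluminium foil (AGA, opaque and airtight) best. Default magnitudes
#' put the PP / 25 deg C trajectory at a peak of roughly 40 meq O2/kg near
#' 150 days while AGA stays near baseline.
#'
#' @param pv0 baseline peroxide value, meq O2/kg.
#' @param k232_0,k268_0 baseline specific extinction coefficients.
#' @param growth_rate per-day primary-oxidation rate g.
#' @param decay_rate per-day peroxide-decomposition rate d.
#' @param pv_amplitude kinetic amplitude A, meq O2/kg.
#' @param k232_slope K232 increase per unit PV increase.
#' @param k268_gain asymptotic K268 rise at r = 1.
#' @param temp_factor named numeric vector: rate multiplier per temperature
#'   level (names are the temperature values).
#' @param material_factor named numeric vector: rate multiplier per material.
#' @param noise_sd measurement noise scale; PV noise has this sd, K232 and
#'   K268 noise are scaled down to 0.1 and 0.04 of it to match their units.
#' @return an object of class `oxidation_params`.
#' @export
oxidation_params <- function(pv0 = 3,
                             k232_0 = 4.26,
                             k268_0 = 1.25,
                             growth_rate = 0.012,
                             decay_rate = 0.002,
                             pv_amplitude = 60,
                             k232_slope = 0.17,
                             k268_gain = 1.45,
                             temp_factor = c("10" = 0.4, "25" = 1),
                             material_factor = c(PP = 1, CG = 0.6, AG = 0.45, AGA = 0.15),
                             noise_sd = 0.5) {
  rates <- c(pv0 = pv0, growth_rate = growth_rate, decay_rate = decay_rate,
             pv_amplitude = pv_amplitude, noise_sd = noise_sd)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates, amplitudes and noise_sd must be finite and >= 0", call. = FALSE)
  }
  if (is.null(names(temp_factor)) || is.null(names(material_factor))) {
    stop("temp_factor and material_factor must be named vectors", call. = FALSE)
  }
  if (any(temp_factor < 0) || any(material_factor < 0)) {
    stop("rate multipliers must be >= 0", call. = FALSE)
  }
  tt <- suppressWarnings(as.numeric(names(temp_factor)))
  if (!anyNA(tt) && is.unsorted(temp_factor[order(tt)], strictly = FALSE)) {
    stop("temp_factor must be non-decreasing in temperature", call. = FALSE)
  }
  std <- c("AGA", "AG", "CG", "PP")
  if (all(std %in% names(material_factor)) &&
      is.unsorted(material_factor[std], strictly = FALSE)) {
    stop("material_factor must satisfy AGA <= AG <= CG <= PP", call. = FALSE)
  }
  structure(
    list(pv0 = pv0, k232_0 = k232_0, k268_0 = k268_0,
         growth_rate = growth_rate, decay_rate = decay_rate,
         pv_amplitude = pv_amplitude, k232_slope = k232_slope,
         k268_gain = k268_gain, temp_factor = temp_factor,
         material_factor = material_factor, noise_sd = noise_sd),
    class = "oxidation_params"
  )
}

# Combined rate multiplier r = temp_factor * material_factor per design row.
combined_rate <- function(design, params) {
  tf <- params$temp_factor[as.character(design$temperature)]
  mf <- params$material_factor[as.character(design$material)]
  if (anyNA(tf)) stop("temp_factor missing a temperature level", call. = FALSE)
  if (anyNA(mf)) stop("material_factor missing a material level", call. = FALSE)
  unname(tf * mf)
}

#' Simulate oxidation chemistry along a storage design
#'
#' Evaluates the kinetic model of [oxidation_params()] for every design row
#' and adds Gaussian measurement noise, truncated at zero (concentrations and
#' extinctions cannot be negative). Deterministic given `seed`.
#'
#' @param design a design table from [generate_design()].
#' @param params an [oxidation_params()] object.
#' @param seed integer RNG seed.
#' @return a `data.frame` with columns `row_id`, `pv` (meq O2/kg), `k232`,
#'   `k268`.
#' @export
#' @examples
#' design <- generate_design(design_spec())
#' chem <- simulate_chemistry(design, oxidation_params(), seed = 1)
#' head(chem)
simulate_chemistry <- function(design, params = oxidation_params(), seed = 1) {
  if (!inherits(params, "oxidation_params")) {
    stop("`params` must be an oxidation_params object", call. = FALSE)
  }
  if (!design_is_balanced(design)) {
    stop("`design` must be a balanced complete factorial", call. = FALSE)
  }
  r <- combined_rate(design, params)
  t <- design$time
  g <- params$growth_rate
  d <- params$decay_rate
  pv_det <- params$pv0 +
    params$pv_amplitude * r * (1 - exp(-g * r * t)) * exp(-d * r * t)
  k232_det <- params$k232_0 + params$k232_slope * (pv_det - params$pv0)
  k268_det <- params$k268_0 + params$k268_gain * r * (1 - exp(-g * r * t))
  n <- nrow(design)
  noise <- with_seed(seed, {
    list(pv = rnorm(n, sd = params$noise_sd),
         k232 = rnorm(n, sd = params$noise_sd * 0.1),
         k268 = rnorm(n, sd = params$noise_sd * 0.04))
  })
  data.frame(
    row_id = design$row_id,
    pv = pmax(0, pv_det + noise$pv),
    k232 = pmax(0, k232_det + noise$k232),
    k268 = pmax(0, k268_det + noise$k268),
    stringsAsFactors = FALSE
  )
}
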