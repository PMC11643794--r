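#' Peroxide value from an iodometric titration
#'
#' The peroxide value of an oil (meq O2 per kg) is the titrant volume in mL
#' times the titrant normality (eq/L, i.e. meq/mL), divided by the sample
#' mass in kg. Vectorized; exactly linear in volume and normality and
#' inversely proportional to mass.
#'
#' @param titrant_volume thiosulfate volume, mL (>= 0).
#' @param titrant_normality titrant normality, eq/L (> 0).
#' @param sample_mass oil mass, kg (> 0).
#' @return peroxide value, meq O2/kg.
#' @export
#' @examples
#' peroxide_value(1, 0.01, 0.002) # 5 meq O2/kg
peroxide_value <- function(titrant_volume, titrant_normality, sample_mass) {
  if (any(titrant_volume < 0)) stop("titrant volume must be >= 0", call. = FALSE)
  if (any(titrant_normality <= 0)) stop("titrant normality must be > 0", call. = FALSE)
  if (any(sample_mass <= 0)) stop("sample mass must be > 0", call. = FALSE)
  titrant_volume * titrant_normality / sample_mass
}

#' Specific extinction coefficient of an oil solution
#'
#' The specific extinction K at a UV wavelength (232 nm for conjugated
#' dienes, 268 nm for trienes) is the measured absorbance divided by the
#' product of solution concentration (g/100 mL) and cuvette path length
#' (cm). The result is reported to two decimal places; rounding is applied
#' once, at output.
#'
#' @param absorbance measured absorbance, AU (>= 0).
#' @param concentration solution concentration, g/100 mL (> 0).
#' @param path_length cuvette path length, cm (> 0).
#' @return the specific extinction coefficient, rounded to 2 decimals.
#' @export
#' @examples
#' # 0.25 g oil in 50 mL (0.5 g/100 mL), 1 cm path:
#' extinction_coefficient(2.13, 0.5, 1) # 4.26
extinction_coefficient <- function(absorbance, concentration, path_length) {
  if (any(absorbance < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (any(concentration <= 0)) stop("concentration must be > 0", call. = FALSE)
  if (any(path_length <= 0)) stop("path length must be > 0", call. = FALSE)
  round(absorbance / (concentration * path_length), 2)
}

#' Fatty-acid class sums
#'
#' Totals the FAME percentages of a fatty-acid composition table by
#' saturation class: saturated (SFA), monounsaturated (MUFA) and
#' polyunsaturated (PUFA).
#'
#' @param fa_table data.frame with columns `class` (in SFA/MUFA/PUFA) and
#'   `percent` (of total FAME, >= 0).
#' @return named numeric vector with entries `SFA`, `MUFA`, `PUFA` (0 for a
#'   class absent from the table).
#' @export
#' @examples
#' fa_class_sums(hemp_fa_composition())
fa_class_sums <- function(fa_table) {
  if (nrow(fa_table) == 0L) stop("fatty-acid table is empty", call. = FALSE)
  classes <- c("SFA", "MUFA", "PUFA")
  if (!all(fa_table$class %in% classes)) {
    bad <- setdiff(unique(fa_table$class), classes)
    stop("unknown fatty-acid class label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(fa_table$percent < 0)) stop("percentages must be >= 0", call. = FALSE)
  sums <- tapply(fa_table$percent, factor(fa_table$class, levels = classes), sum)
  out <- ifelse(is.na(sums), 0, sums)
  names(out) <- classes
  out
}

#' Fatty-acid composition of cold-pressed hempseed oil
#'
#' Reads the bundled reference composition table: 17 fatty acids (as % of
#' total FAME) measured by GC of methyl esters on a fresh cold-pressed
#' hempseed oil, dominated by linoleic (18:2 n-6) and alpha-linolenic
#' (18:3 n-3) acids.
#'
#' @return data.frame with columns `peak`, `fatty_acid`, `class`,
#'   `percent`, `sd`.
#' @export
hemp_fa_composition <- function() {
  path <- system.file("extdata", "hempseed_fatty_acids.csv",
                      package = "oilshelf", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Three-way fixed-effects ANOVA with Tukey post hoc
#'
#' Univariate analysis of one chemistry response over the
#' time x temperature x material design, with main effects and all two-way
#' interactions (the same model terms as the multivariate spectral
#' decomposition, so the sums of squares match [asca_decompose()] applied
#' to a single column). Pairwise level differences per factor are assessed
#' with Tukey's honestly-significant-difference test at family level 0.05.
#'
#' @param y numeric response, one value per design row.
#' @param design balanced design table with replication.
#' @return an object of class `threeway_anova`: `table` (term, df, ssq,
#'   mean square, F, p), `tukey` (named list of Tukey results per main
#'   factor), and `no_variance` flag (TRUE when `y` is constant, in which
#'   case F ratios are undefined).
#' @export
threeway_anova <- function(y, design) {
  y <- as.numeric(y)
  if (length(y) != nrow(design)) {
    stop("`y` must have one value per design row", call. = FALSE)
  }
  if (!design_is_balanced(design)) {
    stop("`design` must be a balanced complete factorial", call. = FALSE)
  }
  f <- asca_factors(design)
  n_cells <- length(levels(f$time)) * length(levels(f$temp)) *
    length(levels(f$mat))
  if (length(y) <= n_cells) {
    stop("no residual degrees of freedom: the design has no replication",
         call. = FALSE)
  }
  dat <- data.frame(y = y, time = f$time, temp = f$temp, mat = f$mat)
  if (var(y) == 0) {
    return(structure(list(table = NULL, tukey = NULL, no_variance = TRUE),
                     class = "threeway_anova"))
  }
  # factors with a single level carry no variance and are dropped from the
  # model formula (aov cannot build contrasts for them)
  active <- names(f)[vapply(f, nlevels, integer(1)) >= 2L]
  if (length(active) == 0L) {
    stop("no design factor has more than one level", call. = FALSE)
  }
  form <- stats::as.formula(
    paste("y ~ (", paste(active, collapse = " + "), ")^2"))
  fit <- aov(form, data = dat)
  sm <- summary(fit)[[1]]
  tab <- data.frame(
    term = trimws(rownames(sm)),
    df = sm$Df,
    ssq = sm$`Sum Sq`,
    mean_sq = sm$`Mean Sq`,
    f_value = sm$`F value`,
    p_value = sm$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  tukey <- TukeyHSD(fit, which = active, conf.level = 0.95)
  structure(list(table = tab, tukey = tukey, no_variance = FALSE),
            class = "threeway_anova")
}

#' @export
print.threeway_anova <- function(x, ...) {
  if (x$no_variance) {
    cat("Three-way ANOVA: response has no variance; F ratios undefined\n")
    return(invisible(x))
  }
  cat("Three-way fixed-effects ANOVA (mains + two-way interactions)\n")
  tab <- x$table
  tab$ssq <- signif(tab$ssq, 4)
  tab$mean_sq <- signif(tab$mean_sq, 4)
  tab$f_value <- signif(tab$f_value, 4)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
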