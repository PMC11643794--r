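#' @name asca-module
#' @title ANOVA-simultaneous component analysis of factorial spectra
#' @description
#' ASCA partitions a column-centered data matrix collected under a balanced
#' factorial design into additive effect matrices, one per experimental
#' factor and two-way interaction,
#' X = mu + X_time + X_temp + X_mat + X_time:temp + X_temp:mat + X_mat:time + E,
#' and then summarizes each effect matrix by PCA (simultaneous component
#' analysis). For a balanced, complete design the effect matrices are
#' mutually orthogonal, so their sums of squares add up to the total.
#' @keywords internal
NULL

asca_effect_names <- c("time", "temp", "mat", "time:temp", "temp:mat", "mat:time")

# Extract the three design factors with stable level order.
asca_factors <- function(design) {
  list(
    time = factor(design$time, levels = sort(unique(design$time))),
    temp = factor(design$temperature, levels = sort(unique(design$temperature))),
    mat = factor(design$material)
  )
}

# Analysis matrix from either a preprocessed_spectra object or a plain
# matrix (centered here if not already).
analysis_matrix <- function(x) {
  if (inherits(x, "preprocessed_spectra")) {
    list(xc = x$matrix, mu = x$grand_mean)
  } else {
    x <- as.matrix(x)
    mu <- colMeans(x)
    list(xc = sweep(x, 2, mu), mu = mu)
  }
}

# Row-expanded group-mean matrix of centered data for one grouping factor.
group_effect <- function(xc, f) {
  m <- rowsum(xc, f)
  m <- m / as.vector(table(f)[rownames(m)])
  m[as.character(f), , drop = FALSE]
}

# Sum of squares explained by the group means of `f` on centered data.
ssq_groups <- function(xc, f) {
  m <- rowsum(xc, f)
  cnt <- as.vector(table(f)[rownames(m)])
  sum(m^2 / cnt)
}

#' Decompose preprocessed spectra into factorial effect matrices
#'
#' Estimates the fixed-effects decomposition of a balanced
#' time x temperature x material experiment. Main-effect rows are the
#' factor-level mean spectra minus the grand mean; two-way interaction rows
#' are the cell means minus both level means plus the grand mean; the
#' residual E collects what remains. For a balanced complete design the
#' decomposition reconstructs the centered matrix exactly and the effect
#' sums of squares are additive.
#'
#' @param x a `preprocessed_spectra` object or a numeric matrix whose rows
#'   align with `design` (a plain matrix is centered internally).
#' @param design design table with columns `time`, `temperature`, `material`.
#' @return an object of class `effect_decomposition`: grand mean `mu`,
#'   named list `effects` (`time`, `temp`, `mat`, `time:temp`, `temp:mat`,
#'   `mat:time`), `residual`, named `ssq` vector (effects plus residual),
#'   and `total_ssq` of the centered matrix.
#' @export
#' @examples
#' sim <- simulate_shelf_life(seed = 1)
#' prep <- preprocess_spectra(sim$spectra)
#' dec <- asca_decompose(prep, sim$design)
#' effect_percentages(dec)
asca_decompose <- function(x, design) {
  am <- analysis_matrix(x)
  xc <- am$xc
  if (nrow(xc) != nrow(design)) {
    stop("rows of `x` must align with rows of `design`", call. = FALSE)
  }
  if (!design_is_balanced(design)) {
    stop("unsupported design: ASCA decomposition requires a balanced, ",
         "complete factorial (the balanced estimator is biased otherwise)",
         call. = FALSE)
  }
  f <- asca_factors(design)
  main <- lapply(f, function(fi) group_effect(xc, fi))
  inter_of <- function(a, b) {
    cell <- group_effect(xc, interaction(f[[a]], f[[b]], drop = TRUE))
    cell - main[[a]] - main[[b]]
  }
  effects <- list(
    "time" = main$time,
    "temp" = main$temp,
    "mat" = main$mat,
    "time:temp" = inter_of("time", "temp"),
    "temp:mat" = inter_of("temp", "mat"),
    "mat:time" = inter_of("mat", "time")
  )
  residual <- xc - Reduce(`+`, effects)
  ssq <- vapply(c(effects, list(residual = residual)), function(m) sum(m^2),
                numeric(1))
  structure(
    list(mu = am$mu, effects = effects, residual = residual,
         ssq = ssq, total_ssq = sum(xc^2), design = design),
    class = "effect_decomposition"
  )
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat("ASCA effect decomposition (", nrow(x$residual), "rows )\n")
  print(round(effect_percentages(x), 2))
  invisible(x)
}

#' Effect percentages of an ASCA decomposition
#'
#' Expresses each effect matrix's sum of squares as a percentage of the
#' total centered sum of squares. For a balanced design the entries
#' (six effects plus residual) sum to 100.
#'
#' @param d an `effect_decomposition`.
#' @return named numeric vector of percentages.
#' @export
effect_percentages <- function(d) {
  if (!inherits(d, "effect_decomposition")) {
    stop("`d` must be an effect_decomposition", call. = FALSE)
  }
  if (d$total_ssq <= 0) {
    stop("total sum of squares is zero; effect percentages are undefined",
         call. = FALSE)
  }
  100 * d$ssq / d$total_ssq
}

#' Simultaneous component analysis of one effect matrix
#'
#' PCA of an effect matrix by singular value decomposition. The number of
#' retained components is the numerical rank (singular values above
#' `tol` times the largest). Scores are the effect rows projected on the
#' loadings; "spider" (augmented) scores additionally project the residual
#' rows added back to the effect, showing within-level dispersion around
#' each level's centroid.
#'
#' @param effect_matrix one effect matrix from [asca_decompose()].
#' @param residual optional residual matrix for augmented scores.
#' @param effect_name label carried into the result.
#' @param tol relative singular-value tolerance for rank detection.
#' @return an object of class `sca_result` with `loadings` (orthonormal
#'   columns), `scores`, `spider_scores`, `variance_fraction` (sums to 1
#'   over retained components) and `n_components`.
#' @export
sca <- function(effect_matrix, residual = NULL, effect_name = NULL,
                tol = 1e-10) {
  effect_matrix <- as.matrix(effect_matrix)
  sv <- svd(effect_matrix)
  if (sv$d[1] <= 0) {
    stop("zero effect matrix: no components to extract", call. = FALSE)
  }
  r <- sum(sv$d > tol * sv$d[1])
  loadings <- sv$v[, seq_len(r), drop = FALSE]
  rownames(loadings) <- colnames(effect_matrix)
  colnames(loadings) <- paste0("PC", seq_len(r))
  scores <- effect_matrix %*% loadings
  spider <- if (!is.null(residual)) (effect_matrix + residual) %*% loadings
  structure(
    list(effect_name = effect_name,
         loadings = loadings,
         scores = scores,
         spider_scores = spider,
         variance_fraction = sv$d[seq_len(r)]^2 / sum(sv$d[seq_len(r)]^2),
         n_components = r),
    class = "sca_result"
  )
}

#' @export
print.sca_result <- function(x, ...) {
  cat("SCA of effect", if (!is.null(x$effect_name)) sQuote(x$effect_name),
      "-", x$n_components, "component(s)\n")
  cat("  variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "), "\n")
  invisible(x)
}

# Observed or permuted sum of squares of one named effect. `perm` permutes
# the tested factor labels (jointly, for an interaction) against the rows.
effect_ssq <- function(xc, f, effect, perm = NULL) {
  parts <- strsplit(effect, ":", fixed = TRUE)[[1]]
  if (!all(parts %in% names(f))) {
    stop("unknown effect name: ", effect, call. = FALSE)
  }
  if (!is.null(perm)) f <- lapply(f, function(fi) fi[perm])
  if (length(parts) == 1L) {
    ssq_groups(xc, f[[parts]])
  } else {
    ssq_groups(xc, interaction(f[[parts[1]]], f[[parts[2]]], drop = TRUE)) -
      ssq_groups(xc, f[[parts[1]]]) - ssq_groups(xc, f[[parts[2]]])
  }
}

# Draw one permutation of 1..n restricted to shuffle only within strata.
strata_permutation <- function(strata) {
  idx <- seq_along(strata)
  for (s in split(idx, strata)) {
    idx[s] <- s[sample.int(length(s))]
  }
  idx
}

#' Permutation significance test for one ASCA effect
#'
#' Tests whether an effect's sum of squares could arise by chance, with a
#' permutation scheme chosen so that variance belonging to the remaining
#' model terms does not inflate the null distribution:
#'
#' * **Main effects** use a restricted (within-stratum) permutation: the
#'   tested factor's labels are shuffled only within the cells of the other
#'   two factors, whose rows are exchangeable under the null. This leaves
#'   the other factors' variance perfectly aligned, so the null
#'   distribution samples only residual-scale variance, and the test is
#'   exact for iid residuals.
#' * **Interactions**, for which no exact restricted scheme exists, are
#'   tested on the reduced-model matrix (the tested effect plus the
#'   residual, i.e. the data with all other terms removed) with free
#'   permutation of the joint factor labels - the standard
#'   permutation-of-residuals-under-the-reduced-model approximation.
#'
#' The empirical p-value uses the floor convention p = max(count, 1)/B with
#' a conservative `>=` comparison, so the smallest attainable p-value is
#' 1/B (0.0002 at B = 5000).
#'
#' @param x `preprocessed_spectra`, a matrix aligned with `design`, or an
#'   `effect_decomposition` already computed from them.
#' @param design design table.
#' @param effect one of `"time"`, `"temp"`, `"mat"`, `"time:temp"`,
#'   `"temp:mat"`, `"mat:time"`.
#' @param B number of permutations (>= 1).
#' @param seed integer RNG seed; results are reproducible given the seed.
#' @return an object of class `permutation_result` with `observed_ssq`,
#'   `permuted_ssq` (length B), `p_value`, `B` and `seed`.
#' @export
#' @examples
#' sim <- simulate_shelf_life(seed = 1)
#' prep <- preprocess_spectra(sim$spectra)
#' asca_permutation(prep, sim$design, "temp", B = 200, seed = 1)
asca_permutation <- function(x, design, effect, B = 5000, seed = 1) {
  if (!is.numeric(B) || B < 1) stop("`B` must be >= 1", call. = FALSE)
  B <- as.integer(B)
  dec <- if (inherits(x, "effect_decomposition")) x else asca_decompose(x, design)
  if (!effect %in% names(dec$effects)) {
    stop("unknown effect name: ", effect, call. = FALSE)
  }
  f <- asca_factors(design)
  parts <- strsplit(effect, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    # restricted permutation on the full centered matrix
    xc <- Reduce(`+`, dec$effects) + dec$residual
    others <- setdiff(names(f), parts)
    strata <- interaction(f[[others[1]]], f[[others[2]]], drop = TRUE)
    observed <- ssq_groups(xc, f[[parts]])
    permuted <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        ssq_groups(xc, f[[parts]][strata_permutation(strata)])
      }, numeric(1))
    })
  } else {
    # free permutation on the reduced-model matrix
    reduced <- dec$effects[[effect]] + dec$residual
    n <- nrow(reduced)
    observed <- effect_ssq(reduced, f, effect)
    permuted <- with_seed(seed, {
      vapply(seq_len(B),
             function(b) effect_ssq(reduced, f, effect, perm = sample.int(n)),
             numeric(1))
    })
  }
  p <- max(sum(permuted >= observed), 1L) / B
  structure(
    list(effect_name = effect, observed_ssq = observed,
         permuted_ssq = permuted, p_value = p, B = B, seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test for effect", sQuote(x$effect_name), "\n")
  cat(sprintf("  observed SSQ = %.4g, B = %d, p = %.4g\n",
              x$observed_ssq, x$B, x$p_value))
  invisible(x)
}

#' Full ASCA analysis: decomposition, SCA per effect, permutation tests
#'
#' Runs the complete ASCA workflow and assembles an effects table with, for
#' each model term, the number of simultaneous components (numerical rank of
#' the effect matrix), the effect percentage of total centered variance, and
#' the permutation p-value.
#'
#' @param x `preprocessed_spectra` or matrix aligned with `design`.
#' @param design design table.
#' @param permutations permutations per effect (B).
#' @param seed integer RNG seed; effect `i` uses `seed + i`.
#' @return an object of class `asca_result`: `effects_table` (data.frame),
#'   `decomposition`, `sca` (named list of `sca_result`), `permutation`
#'   (named list of `permutation_result`).
#' @export
asca <- function(x, design, permutations = 5000, seed = 1) {
  dec <- asca_decompose(x, design)
  pct <- effect_percentages(dec)
  scas <- lapply(asca_effect_names, function(e) {
    sca(dec$effects[[e]], dec$residual, effect_name = e)
  })
  names(scas) <- asca_effect_names
  perms <- lapply(seq_along(asca_effect_names), function(i) {
    asca_permutation(dec, design, asca_effect_names[i], B = permutations,
                     seed = seed + i)
  })
  names(perms) <- asca_effect_names
  tab <- data.frame(
    effect = c(asca_effect_names, "residual"),
    n_components = c(vapply(scas, function(s) s$n_components, integer(1)), NA),
    effect_pct = unname(pct[c(asca_effect_names, "residual")]),
    p_value = c(vapply(perms, function(p) p$p_value, numeric(1)), NA),
    stringsAsFactors = FALSE
  )
  structure(
    list(effects_table = tab, decomposition = dec, sca = scas,
         permutation = perms),
    class = "asca_result"
  )
}

#' @export
print.asca_result <- function(x, ...) {
  cat("ASCA analysis\n")
  tab <- x$effects_table
  tab$effect_pct <- round(tab$effect_pct, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
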