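test_that("the decomposition reproduces hand-computed cell means on a 2x2 toy", {
  spec <- design_spec(time_levels = c(1, 2), temperature_levels = c(10, 25),
                      material_levels = "M", n_replicates = 1)
  design <- generate_design(spec)
  # values 1..4 laid out over the (time, temperature) cells
  val <- with(design, ifelse(time == 1 & temperature == 10, 1,
                      ifelse(time == 1 & temperature == 25, 2,
                      ifelse(time == 2 & temperature == 10, 3, 4))))
  x <- matrix(val, ncol = 1, dimnames = list(design$row_id, "5000"))
  dec <- asca_decompose(x, design)
  expect_equal(unname(dec$effects$time[, 1]),
               ifelse(design$time == 1, -1, 1))
  expect_equal(unname(dec$effects$temp[, 1]),
               ifelse(design$temperature == 10, -0.5, 0.5))
  expect_true(all(abs(dec$effects$`time:temp`) < 1e-12))
  expect_true(all(abs(dec$residual) < 1e-12))
})

test_that("identical rows decompose to nothing", {
  design <- generate_design(tiny_spec())
  x <- matrix(rep(c(1, 2, 3), each = nrow(design)), nrow(design), 3,
              dimnames = list(design$row_id, c(100, 200, 300)))
  dec <- asca_decompose(x, design)
  expect_true(all(vapply(dec$effects, function(m) max(abs(m)), 1) < 1e-12))
  expect_lt(max(abs(dec$residual)), 1e-12)
  expect_error(effect_percentages(dec), "undefined")
})

test_that("unbalanced designs are rejected", {
  design <- generate_design(tiny_spec())
  x <- matrix(rnorm(nrow(design) * 3), nrow(design), 3,
              dimnames = list(design$row_id, c(100, 200, 300)))
  expect_error(asca_decompose(x[-1, ], design[-1, ]), "balanced")
  expect_error(asca_decompose(x[-1, ], design), "align")
})

test_that("reconstruction and SSQ additivity hold on random datasets", {
  for (seed in 1:5) {
    set.seed(seed)
    spec <- tiny_spec(times = c(1, 5, 9), reps = 2)
    design <- generate_design(spec)
    x <- matrix(rnorm(nrow(design) * 7), nrow(design), 7,
                dimnames = list(design$row_id, 101:107))
    dec <- asca_decompose(x, design)
    xc <- sweep(x, 2, colMeans(x))
    recon <- Reduce(`+`, dec$effects) + dec$residual
    expect_lt(max(abs(recon - xc)) / max(abs(xc)), 1e-8)
    expect_lt(abs(sum(dec$ssq) - dec$total_ssq) / dec$total_ssq, 1e-8)
    expect_equal(sum(effect_percentages(dec)), 100, tolerance = 1e-8)
  }
})

test_that("univariate decomposition matches the brute-force ANOVA oracle", {
  spec <- design_spec(time_levels = c(1, 2, 3), temperature_levels = c(10, 25),
                      material_levels = c("A", "B"), n_replicates = 2)
  design <- generate_design(spec)
  set.seed(11)
  y <- rnorm(nrow(design))
  x <- matrix(y, ncol = 1, dimnames = list(design$row_id, "5000"))
  dec <- asca_decompose(x, design)
  oracle <- oracle_anova_ssq(y, design$time, design$temperature,
                             as.character(design$material))
  expect_equal(dec$ssq[names(oracle)], oracle, tolerance = 1e-10)
})

test_that("effect matrix ranks respect the design degrees of freedom", {
  sim <- default_sim()
  prep <- preprocess_spectra(sim$spectra)
  dec <- asca_decompose(prep, sim$design)
  df <- c("time" = 8, "temp" = 1, "mat" = 3,
          "time:temp" = 8, "temp:mat" = 3, "mat:time" = 24)
  for (e in names(df)) {
    s <- sca(dec$effects[[e]], dec$residual, effect_name = e)
    expect_lte(s$n_components, df[[e]])
    expect_equal(sum(s$variance_fraction), 1, tolerance = 1e-12)
    expect_equal(unname(crossprod(s$loadings)),
                 diag(s$n_components), tolerance = 1e-10)
  }
})

test_that("SCA recovers a planted rank-1 effect exactly", {
  u <- rep(c(-1, 1), each = 4)
  v <- c(3, 1, -2, 0.5)
  m <- u %*% t(v)
  colnames(m) <- c(100, 200, 300, 400)
  s <- sca(m)
  expect_equal(s$n_components, 1)
  expect_equal(s$variance_fraction, 1)
  expect_equal(abs(sum(s$loadings[, 1] * v / sqrt(sum(v^2)))), 1,
               tolerance = 1e-12)
  expect_error(sca(m * 0), "zero effect")
})

test_that("effect percentages recover a planted variance split", {
  pure <- two_factor_signal(noise_sd = 0)
  dec <- asca_decompose(pure$x, pure$design)
  pct <- effect_percentages(dec)
  expect_equal(unname(pct["time"] / pct["temp"]), 4, tolerance = 1e-10)
  expect_equal(unname(pct["time"] + pct["temp"]), 100, tolerance = 1e-10)

  noisy <- two_factor_signal(noise_sd = 0.3, seed = 42)
  pct2 <- effect_percentages(asca_decompose(noisy$x, noisy$design))
  expect_equal(unname(pct2["time"] / pct2["temp"]), 4, tolerance = 0.2)

  # a single-factor signal owns all the variance
  spec <- tiny_spec()
  design <- generate_design(spec)
  x <- matrix(ifelse(design$temperature == 10, -1, 1), ncol = 1,
              dimnames = list(design$row_id, "5000"))
  pct3 <- effect_percentages(asca_decompose(x, design))
  expect_equal(unname(pct3["temp"]), 100, tolerance = 1e-10)
  expect_lt(max(pct3[setdiff(names(pct3), "temp")]), 1e-10)
})

test_that("the permutation test is seeded, floored and degenerate-safe", {
  design <- generate_design(tiny_spec())
  # constant matrix: every permuted statistic ties the observed zero
  x0 <- matrix(5, nrow(design), 3, dimnames = list(design$row_id, c(100, 200, 300)))
  p0 <- asca_permutation(x0, design, "temp", B = 99, seed = 1)
  expect_equal(p0$p_value, 1)

  set.seed(2)
  x <- matrix(rnorm(nrow(design) * 4), nrow(design), 4,
              dimnames = list(design$row_id, 101:104))
  r1 <- asca_permutation(x, design, "time", B = 50, seed = 9)
  r2 <- asca_permutation(x, design, "time", B = 50, seed = 9)
  expect_identical(r1$permuted_ssq, r2$permuted_ssq)
  expect_gte(r1$p_value, 1 / 50)
  expect_lte(r1$p_value, 1)

  expect_error(asca_permutation(x, design, "flavor", B = 10), "unknown effect")
})

test_that("permutation p-values are calibrated on null data", {
  spec <- tiny_spec(times = c(1, 2), reps = 2)
  design <- generate_design(spec)
  n_sim <- 150
  hits <- 0
  pvals <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    set.seed(1000 + i)
    x <- matrix(rnorm(nrow(design) * 4), nrow(design), 4,
                dimnames = list(design$row_id, 101:104))
    pvals[i] <- asca_permutation(x, design, "temp", B = 200,
                                 seed = 2000 + i)$p_value
  }
  frac <- mean(pvals <= 0.05)
  # three binomial standard errors around the nominal level
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(frac - 0.05), 3 * se + 1 / 200)
  # p-values roughly uniform on (0, 1]
  expect_gt(mean(pvals), 0.40)
  expect_lt(mean(pvals), 0.60)
})

test_that("a strong planted effect drives the p-value to the 1/B floor", {
  sim <- default_sim()
  prep <- preprocess_spectra(sim$spectra)
  pr <- asca_permutation(prep, sim$design, "temp", B = 500, seed = 3)
  expect_equal(pr$p_value, 1 / 500)
})

test_that("the asca wrapper assembles a coherent effects table", {
  sim <- default_sim()
  prep <- preprocess_spectra(sim$spectra)
  res <- asca(prep, sim$design, permutations = 50, seed = 1)
  tab <- res$effects_table
  expect_equal(tab$effect,
               c("time", "temp", "mat", "time:temp", "temp:mat", "mat:time",
                 "residual"))
  expect_equal(sum(tab$effect_pct), 100, tolerance = 1e-8)
  expect_true(all(tab$p_value[1:6] >= 1 / 50 & tab$p_value[1:6] <= 1))
  expect_equal(tab$n_components[1:3], c(8, 1, 3))
  # spider scores project effect + residual rows for every sample
  expect_equal(nrow(res$sca$temp$spider_scores), nrow(sim$design))
})
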