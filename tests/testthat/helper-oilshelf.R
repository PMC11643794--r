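# Shared fixtures and independent oracles for the test suite.

# Small balanced designs used across tests.
tiny_spec <- function(times = c(10, 100), temps = c(10, 25),
                      mats = c("PP", "AGA"), reps = 2) {
  design_spec(time_levels = times, temperature_levels = temps,
              material_levels = mats, n_replicates = reps)
}

# A modest full dataset shared by several files (built once per test run).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_shelf_life(seed = 1)
    cache
  }
})

# Independent brute-force oracle for balanced fixed-effects sums of squares:
# explicit cell-mean arithmetic with loops, no shared code with the package.
oracle_anova_ssq <- function(y, a, b, c) {
  gm <- mean(y)
  ss_main <- function(f) {
    s <- 0
    for (l in unique(f)) s <- s + sum(f == l) * (mean(y[f == l]) - gm)^2
    s
  }
  ss_int <- function(f1, f2) {
    s <- 0
    for (l1 in unique(f1)) {
      for (l2 in unique(f2)) {
        idx <- f1 == l1 & f2 == l2
        s <- s + sum(idx) *
          (mean(y[idx]) - mean(y[f1 == l1]) - mean(y[f2 == l2]) + gm)^2
      }
    }
    s
  }
  ss <- c(
    time = ss_main(a), temp = ss_main(b), mat = ss_main(c),
    "time:temp" = ss_int(a, b), "temp:mat" = ss_int(b, c),
    "mat:time" = ss_int(c, a)
  )
  c(ss, residual = sum((y - gm)^2) - sum(ss))
}

# Single-column dataset with a known 4:1 time:temp variance split plus
# optional iid noise. Enough replication that the Monte-Carlo error of the
# recovered split is small against the planted ratio.
two_factor_signal <- function(noise_sd = 0, seed = 42) {
  spec <- design_spec(time_levels = c(1, 2), temperature_levels = c(10, 25),
                      material_levels = "M", n_replicates = 16)
  design <- generate_design(spec)
  u_time <- ifelse(design$time == 1, -1, 1)
  u_temp <- ifelse(design$temperature == 10, -1, 1)
  x <- matrix(2 * u_time + 1 * u_temp, ncol = 1,
              dimnames = list(design$row_id, "5000"))
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + matrix(rnorm(nrow(x), sd = noise_sd), ncol = 1)
  }
  list(x = x, design = design)
}
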