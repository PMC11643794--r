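#' Fit a single-response PLS regression (NIPALS PLS1)
#'
#' Partial least squares extracts latent variables - linear combinations of
#' the spectral channels chosen to maximize covariance with the response -
#' and regresses the response on them. The single-response NIPALS algorithm
#' is deterministic: weights are the normalized covariance X'y of the
#' deflated data, scores are orthogonal by construction, and the prediction
#' is affine in the input spectrum.
#'
#' @param x numeric matrix (rows = samples) or `preprocessed_spectra`.
#' @param y numeric response vector.
#' @param n_lv number of latent variables, at most `min(nrow - 1, ncol)`.
#' @return an object of class `pls_model` with centering terms (`x_mean`,
#'   `y_mean`), `x_weights`, `x_loadings`, `y_loadings`, per-LV-count
#'   regression vectors (`coefficients`, one column per model size) and
#'   `scores`.
#' @export
#' @examples
#' sim <- simulate_shelf_life(seed = 1)
#' prep <- preprocess_spectra(sim$spectra)
#' fit <- fit_pls(prep$matrix, sim$chemistry$pv, n_lv = 5)
#' cor(predict(fit), sim$chemistry$pv)
fit_pls <- function(x, y, n_lv) {
  if (inherits(x, "preprocessed_spectra")) x <- x$matrix
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop("`y` must have one value per row of `x`", call. = FALSE)
  if (n_lv < 1 || n_lv > min(n - 1, p)) {
    stop("`n_lv` must be between 1 and min(rows - 1, channels)", call. = FALSE)
  }
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  e <- sweep(x, 2, x_mean)
  fres <- y - y_mean
  w_mat <- matrix(0, p, n_lv)
  p_mat <- matrix(0, p, n_lv)
  q_vec <- numeric(n_lv)
  t_mat <- matrix(0, n, n_lv)
  eps <- .Machine$double.eps^0.5
  for (a in seq_len(n_lv)) {
    w <- crossprod(e, fres)
    nw <- sqrt(sum(w^2))
    if (nw < eps * max(1, sqrt(sum(fres^2)))) {
      stop("`n_lv` exceeds the rank of the data (component ", a,
           " has no covariance left)", call. = FALSE)
    }
    w <- w / nw
    tt <- e %*% w
    tt2 <- sum(tt^2)
    if (tt2 < eps) stop("degenerate score vector at component ", a, call. = FALSE)
    pp <- crossprod(e, tt) / tt2
    qq <- sum(fres * tt) / tt2
    e <- e - tt %*% t(pp)
    fres <- fres - tt * qq
    w_mat[, a] <- w
    p_mat[, a] <- pp
    q_vec[a] <- qq
    t_mat[, a] <- tt
  }
  # regression vector for every truncated model size
  coefs <- matrix(0, p, n_lv)
  for (a in seq_len(n_lv)) {
    wa <- w_mat[, seq_len(a), drop = FALSE]
    pa <- p_mat[, seq_len(a), drop = FALSE]
    coefs[, a] <- wa %*% solve(crossprod(pa, wa), q_vec[seq_len(a)])
  }
  rownames(coefs) <- colnames(x)
  structure(
    list(n_lv = n_lv, x_weights = w_mat, x_loadings = p_mat,
         y_loadings = q_vec, scores = t_mat, coefficients = coefs,
         x_mean = x_mean, y_mean = y_mean),
    class = "pls_model"
  )
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix of spectra; if omitted, fitted values for the
#'   training data are returned (from the stored scores).
#' @param n_lv model size to use (defaults to the fitted maximum).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata = NULL, n_lv = object$n_lv, ...) {
  if (is.null(newdata)) {
    # training predictions from stored scores
    return(as.numeric(object$scores[, seq_len(n_lv), drop = FALSE] %*%
                        object$y_loadings[seq_len(n_lv)]) + object$y_mean)
  }
  if (inherits(newdata, "preprocessed_spectra")) newdata <- newdata$matrix
  newdata <- as.matrix(newdata)
  if (n_lv < 1 || n_lv > object$n_lv) {
    stop("`n_lv` must be between 1 and the fitted number of components",
         call. = FALSE)
  }
  as.numeric(sweep(newdata, 2, object$x_mean) %*%
               object$coefficients[, n_lv]) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS1 model:", x$n_lv, "latent variable(s),",
      length(x$x_mean), "channels\n")
  invisible(x)
}

#' Leave-one-material-out cross-validation of a PLS calibration
#'
#' Fits PLS models of size 1..`n_lv` and evaluates them by leaving out one
#' packaging-material group at a time: the model is refit on the remaining
#' materials (centering recomputed within each training fold) and predicts
#' the held-out rows. Reported metrics at `n_lv`: RMSEC and RMSECV, R2 of
#' calibration and cross-validation, bias (mean signed cross-validation
#' error, predicted minus observed), and RPD = sd(y)/RMSECV.
#'
#' @param x spectra matrix or `preprocessed_spectra`.
#' @param y numeric response (one value per row).
#' @param design design table supplying the `material` grouping.
#' @param n_lv largest model size to evaluate.
#' @return an object of class `cal_metrics`: point metrics at `n_lv`
#'   (`rmsec`, `rmsecv`, `r2_cal`, `r2_cv`, `bias`, `rpd`), `sd_y`, and
#'   `per_lv` - a data.frame of all metrics against model size.
#' @export
crossval_material <- function(x, y, design, n_lv) {
  if (inherits(x, "preprocessed_spectra")) x <- x$matrix
  x <- as.matrix(x)
  y <- as.numeric(y)
  materials <- as.character(design$material)
  levels_m <- unique(materials)
  if (length(levels_m) < 3L) {
    stop("cross-validation needs >= 2 training materials per fold ",
         "(>= 3 material levels overall)", call. = FALSE)
  }
  full <- fit_pls(x, y, n_lv)
  pred_cal <- vapply(seq_len(n_lv), function(a) predict(full, x, n_lv = a),
                     numeric(length(y)))
  pred_cv <- matrix(NA_real_, length(y), n_lv)
  for (m in levels_m) {
    hold <- materials == m
    fold <- fit_pls(x[!hold, , drop = FALSE], y[!hold], n_lv)
    pred_cv[hold, ] <- vapply(
      seq_len(n_lv),
      function(a) predict(fold, x[hold, , drop = FALSE], n_lv = a),
      numeric(sum(hold))
    )
  }
  rmse <- function(pred) sqrt(colMeans((pred - y)^2))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- function(pred) 1 - colSums((pred - y)^2) / ss_tot
  sd_y <- sd(y)
  per_lv <- data.frame(
    lv = seq_len(n_lv),
    rmsec = rmse(pred_cal),
    rmsecv = rmse(pred_cv),
    r2_cal = r2(pred_cal),
    r2_cv = r2(pred_cv),
    bias = colMeans(pred_cv - y),
    rpd = sd_y / rmse(pred_cv)
  )
  at <- per_lv[n_lv, ]
  structure(
    list(n_lv = n_lv, rmsec = at$rmsec, rmsecv = at$rmsecv,
         r2_cal = at$r2_cal, r2_cv = at$r2_cv, bias = at$bias,
         rpd = at$rpd, sd_y = sd_y, per_lv = per_lv, model = full),
    class = "cal_metrics"
  )
}

#' @export
print.cal_metrics <- function(x, ...) {
  cat(sprintf(
    "PLS calibration (%d LV): RMSEC %.3g, RMSECV %.3g, R2cal %.3f, R2cv %.3f, bias %.3g, RPD %.2f\n",
    x$n_lv, x$rmsec, x$rmsecv, x$r2_cal, x$r2_cv, x$bias, x$rpd))
  invisible(x)
}

#' Ratio of performance to deviation
#'
#' RPD compares the spread of the reference values with the
#' cross-validation error: `sd_ref / rmsecv`. Values above ~3 indicate a
#' calibration fit for quantitative use; 1.5-3 for screening.
#'
#' @param sd_ref standard deviation of the reference values.
#' @param rmsecv root-mean-square error of cross-validation (> 0).
#' @return the RPD.
#' @export
#' @examples
#' rpd(7.60, 2.50) # 3.04
rpd <- function(sd_ref, rmsecv) {
  if (any(rmsecv <= 0)) stop("`rmsecv` must be > 0", call. = FALSE)
  sd_ref / rmsecv
}

#' Choose the number of latent variables from an RMSECV curve
#'
#' Returns the model size minimizing RMSECV; ties break to the smaller
#' (more parsimonious) size.
#'
#' @param curves a `cal_metrics` object, its `per_lv` data.frame, or a bare
#'   numeric RMSECV vector indexed by model size.
#' @return the selected number of latent variables.
#' @export
select_lv <- function(curves) {
  rmsecv <- if (inherits(curves, "cal_metrics")) {
    curves$per_lv$rmsecv
  } else if (is.data.frame(curves)) {
    curves$rmsecv
  } else {
    as.numeric(curves)
  }
  if (length(rmsecv) == 0L) stop("empty RMSECV curve", call. = FALSE)
  which.min(rmsecv)
}

#' Calibrate a response against spectra with automatic model-size choice
#'
#' Runs [crossval_material()] over model sizes 1..`max_lv`, selects the
#' RMSECV-minimizing size with [select_lv()], and reports the metrics at
#' that size (the full per-size curves are kept).
#'
#' @param x spectra matrix or `preprocessed_spectra`.
#' @param y numeric response.
#' @param design design table with the `material` grouping.
#' @param max_lv largest model size scanned.
#' @return a `cal_metrics` object evaluated at the selected size, with the
#'   selected size in `n_lv`.
#' @export
#' @examples
#' sim <- simulate_shelf_life(seed = 1)
#' prep <- preprocess_spectra(sim$spectra)
#' cal <- pls_calibrate(prep, sim$chemistry$pv, sim$design, max_lv = 8)
#' cal
pls_calibrate <- function(x, y, design, max_lv = 12) {
  cv <- crossval_material(x, y, design, n_lv = max_lv)
  best <- select_lv(cv)
  at <- cv$per_lv[best, ]
  cv$n_lv <- best
  cv$rmsec <- at$rmsec
  cv$rmsecv <- at$rmsecv
  cv$r2_cal <- at$r2_cal
  cv$r2_cv <- at$r2_cv
  cv$bias <- at$bias
  cv$rpd <- at$rpd
  cv
}
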