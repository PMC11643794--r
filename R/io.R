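#' Write a spectra matrix to CSV
#'
#' The on-disk dialect is: first column `row_id`, remaining columns named by
#' wavenumber (cm^-1). [read_spectra_csv()] reads it back bit-exactly
#' (values are written with full precision).
#'
#' @param spectra numeric matrix with row names (ids) and numeric column
#'   names (wavenumbers).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  spectra <- as.matrix(spectra)
  ids <- rownames(spectra) %||% sprintf("S%03d", seq_len(nrow(spectra)))
  # 17 significant digits round-trip a double exactly through the parser
  chr <- matrix(formatC(spectra, digits = 17, format = "g"),
                nrow(spectra), ncol(spectra))
  lines <- c(
    paste(c("row_id", colnames(spectra)), collapse = ","),
    paste(ids, apply(chr, 1, paste, collapse = ","), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a spectra matrix from CSV
#'
#' Expects the dialect of [write_spectra_csv()]: a `row_id` column followed
#' by columns whose names are numeric wavenumbers forming a strictly
#' monotone grid. Parse problems (non-numeric header, duplicate ids,
#' ragged rows) raise errors naming the offender.
#'
#' @param path CSV file path.
#' @return numeric matrix with row ids as row names and wavenumbers as
#'   column names.
#' @export
read_spectra_csv <- function(path) {
  df <- tryCatch(
    read.csv(path, check.names = FALSE, comment.char = "#", fill = FALSE,
             stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(df) < 2L) stop(path, ": need a row_id column plus channels", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop(path, ": duplicated row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  wn <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (anyNA(wn)) {
    stop(path, ": non-numeric wavenumber header(s): ",
         paste(colnames(df)[-1][is.na(wn)], collapse = ", "), call. = FALSE)
  }
  d <- diff(wn)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop(path, ": wavenumber grid must be strictly monotone", call. = FALSE)
  }
  x <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(x)) stop(path, ": non-numeric absorbance values", call. = FALSE)
  dimnames(x) <- list(ids, colnames(df)[-1])
  x
}

#' Read/write design and chemistry tables
#'
#' Thin CSV wrappers with column validation for the two tabular inputs:
#' the design table (`row_id`, `time`, `temperature`, `material`,
#' `replicate`) and the reference-chemistry table (`row_id`, `pv`, `k232`,
#' `k268`).
#'
#' @param path CSV file path.
#' @param design,chem the table to write.
#' @return the table (readers) or `path`, invisibly (writers).
#' @name table-io
NULL

#' @rdname table-io
#' @export
read_design_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("row_id", "time", "temperature", "material", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$material <- factor(df$material, levels = unique(df$material))
  df
}

#' @rdname table-io
#' @export
write_design_csv <- function(design, path) {
  write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table-io
#' @export
read_chemistry_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("row_id", "pv", "k232", "k268")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname table-io
#' @export
write_chemistry_csv <- function(chem, path) {
  write.csv(chem, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Configuration of an end-to-end pipeline run
#'
#' Collects everything [run_pipeline()] needs: either paths to existing
#' spectra/design/chemistry CSVs or (when all three are `NULL`) the request
#' to simulate a default dataset; the preprocessing threshold; the
#' permutation count and master seed; and the maximum PLS model size.
#'
#' @param output_dir directory for all artifacts (created if missing).
#' @param spectra_path,design_path,chemistry_path input CSVs; leave all
#'   `NULL` to simulate.
#' @param threshold saturation-masking threshold, AU.
#' @param permutations ASCA permutation count (>= 1).
#' @param seed master integer seed for simulation and permutation tests.
#' @param max_lv largest PLS model size scanned.
#' @return an object of class `run_config`.
#' @export
run_config <- function(output_dir,
                       spectra_path = NULL, design_path = NULL,
                       chemistry_path = NULL,
                       threshold = 2.5, permutations = 5000, seed = 1,
                       max_lv = 12) {
  if (permutations < 1) stop("`permutations` must be >= 1", call. = FALSE)
  paths <- c(spectra_path, design_path, chemistry_path)
  simulate <- is.null(spectra_path) && is.null(design_path) &&
    is.null(chemistry_path)
  if (!simulate) {
    if (is.null(spectra_path) || is.null(design_path) || is.null(chemistry_path)) {
      stop("provide all three input paths, or none to simulate", call. = FALSE)
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("input file(s) not found: ",
                              paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(output_dir = output_dir, spectra_path = spectra_path,
         design_path = design_path, chemistry_path = chemistry_path,
         simulate = simulate, threshold = threshold,
         permutations = as.integer(permutations), seed = as.integer(seed),
         max_lv = as.integer(max_lv)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching the arguments of
#'   [run_config()].
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop(path, ": unknown config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(run_config, cfg)
}

# Write a data.frame as CSV with a leading config-hash comment line.
write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config ", hash), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Run one pipeline stage, prefixing any error with the stage name.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", stage, "]: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full shelf-life analysis pipeline
#'
#' Executes simulate (optional) -> preprocess -> ASCA -> PLS calibration ->
#' chemistry ANOVA, writing all artifacts to the configured output
#' directory: the simulated (or copied-through) data tables, an effects
#' table mirroring the ASCA report (effect, components, effect %, p-value),
#' PC1 loadings and spider scores per main factor, PLS metrics and per-size
#' error curves for PV/K232/K268, the PV ANOVA table, the config as YAML,
#' and a run log recording the seed, permutation count, LV choices and the
#' config hash stamped on every CSV. Identical config and seed give
#' identical outputs.
#'
#' @param config a [run_config()] object (or path to a YAML config).
#' @return invisibly, a list with the in-memory results (`data`,
#'   `preprocessed`, `asca`, `pls`, `anova`) and the written `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    stop("`config` must be a run_config or a YAML path", call. = FALSE)
  }
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out, "config.yaml")
  cfg_list <- unclass(config)
  yaml::write_yaml(cfg_list[!vapply(cfg_list, is.null, logical(1))], cfg_path)
  hash <- unname(tools::md5sum(cfg_path))

  data <- run_stage("data", {
    if (config$simulate) {
      sim <- simulate_shelf_life(seed = config$seed)
      write_spectra_csv(sim$spectra, file.path(out, "spectra.csv"))
      write_design_csv(sim$design, file.path(out, "design.csv"))
      write_chemistry_csv(sim$chemistry, file.path(out, "chemistry.csv"))
      sim
    } else {
      list(spectra = read_spectra_csv(config$spectra_path),
           design = read_design_csv(config$design_path),
           chemistry = read_chemistry_csv(config$chemistry_path))
    }
  })

  prep <- run_stage("preprocess",
                    preprocess_spectra(data$spectra, threshold = config$threshold))

  asca_res <- run_stage("asca",
                        asca(prep, data$design,
                             permutations = config$permutations,
                             seed = config$seed))
  write_csv_hashed(asca_res$effects_table,
                   file.path(out, "effects_table.csv"), hash)
  loadings <- data.frame(
    wavenumber = prep$wavenumbers,
    time = asca_res$sca$time$loadings[, 1],
    temp = asca_res$sca$temp$loadings[, 1],
    mat = asca_res$sca$mat$loadings[, 1]
  )
  write_csv_hashed(loadings, file.path(out, "loadings_pc1.csv"), hash)
  for (e in c("time", "temp", "mat")) {
    sc <- asca_res$sca[[e]]$spider_scores
    df <- data.frame(row_id = data$design$row_id,
                     level = data$design[[c(time = "time", temp = "temperature",
                                            mat = "material")[e]]],
                     sc, check.names = FALSE)
    write_csv_hashed(df, file.path(out, paste0("scores_", e, ".csv")), hash)
  }

  responses <- c(pv = "pv", k232 = "k232", k268 = "k268")
  pls_res <- run_stage("pls", lapply(responses, function(r) {
    pls_calibrate(prep, data$chemistry[[r]], data$design,
                  max_lv = config$max_lv)
  }))
  metrics <- do.call(rbind, lapply(names(pls_res), function(r) {
    m <- pls_res[[r]]
    data.frame(response = r, mean = mean(data$chemistry[[r]]),
               sd = m$sd_y, lv = m$n_lv, rmsec = m$rmsec,
               rmsecv = m$rmsecv, r2_cal = m$r2_cal, bias = m$bias,
               r2_cv = m$r2_cv, rpd = m$rpd)
  }))
  write_csv_hashed(metrics, file.path(out, "pls_metrics.csv"), hash)
  curves <- do.call(rbind, lapply(names(pls_res), function(r) {
    cbind(response = r, pls_res[[r]]$per_lv)
  }))
  write_csv_hashed(curves, file.path(out, "pls_curves.csv"), hash)

  anova_res <- run_stage("anova",
                         threeway_anova(data$chemistry$pv, data$design))
  write_csv_hashed(anova_res$table, file.path(out, "anova_pv.csv"), hash)

  log_path <- file.path(out, "run_log.txt")
  writeLines(c(
    paste0("oilshelf version: ", as.character(packageVersion("oilshelf"))),
    paste0("config hash: ", hash),
    paste0("seed: ", config$seed),
    paste0("permutations: ", config$permutations),
    paste0("saturation threshold: ", config$threshold),
    paste0("selected LVs: ",
           paste(sprintf("%s=%d", names(pls_res),
                         vapply(pls_res, function(m) m$n_lv, integer(1))),
                 collapse = ", "))
  ), log_path)

  files <- list.files(out, full.names = TRUE)
  invisible(list(data = data, preprocessed = prep, asca = asca_res,
                 pls = pls_res, anova = anova_res, files = files,
                 config_hash = hash))
}
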