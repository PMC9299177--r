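# Tabular file I/O and the end-to-end pipeline runner.

#' Read a measurement CSV
#'
#' One row per individual; columns exactly [measurement_schema()]
#' (comma-separated, UTF-8, dot decimal, mm). Rows with missing, non-numeric
#' or non-positive cells are rejected with row/column diagnostics.
#'
#' @param path CSV path.
#' @return A validated [as_measurement_table()].
#' @export
read_measurement_csv <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  schema <- measurement_schema()
  unknown <- setdiff(names(df), schema)
  .assert(length(unknown) == 0,
          paste0("unknown column(s): ", paste(unknown, collapse = ", ")))
  missing_cols <- setdiff(schema, names(df))
  .assert(length(missing_cols) == 0,
          paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  for (nm in setdiff(schema, c("individual_id", "sex"))) {
    v <- df[[nm]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value '%s' at row %d, column %s",
                     v[bad[1]], bad[1], nm), call. = FALSE)
      df[[nm]] <- conv
    }
    bad <- which(is.na(df[[nm]]))
    if (length(bad) > 0)
      stop(sprintf("missing value at row %d, column %s", bad[1], nm),
           call. = FALSE)
  }
  as_measurement_table(df)
}

#' Write a measurement CSV at full precision
#'
#' @param x A measurement table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(x, path) {
  x <- as_measurement_table(x)
  out <- x
  for (nm in setdiff(measurement_schema(), c("individual_id", "sex")))
    out[[nm]] <- sprintf("%.17g", x[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a pairwise dataset or a classifier metrics report as CSV
#'
#' Undefined metrics (`NA`) are rendered as `"n.a."`, matching the reporting
#' convention for classifiers that never emit a positive prediction.
#'
#' @param x Data frame ([build_pairwise_dataset()] output or
#'   [evaluate_classifiers()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(x, path) {
  out <- as.data.frame(x)
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- "n.a."
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed Master seed; every stochastic stage derives its stream from it.
#' @param out_dir Output directory (created if absent).
#' @param n_individuals Simulated population size for the osteometric arm.
#' @param families Classifier families to evaluate.
#' @param cv_folds Cross-validation folds.
#' @param n_match,n_mismatch RMS draws for the screening arm (scalars or
#'   named `c(male=, female=)` vectors, see [simulate_rms()]).
#' @param measurement_csv Optional path to a real measurement CSV; if given,
#'   it replaces the simulated population.
#' @param rtem_threshold rTEM acceptability threshold (%).
#' @param alpha Significance level for group statistics.
#' @return Named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("craniosort_run_"),
                           n_individuals = 150,
                           families = c("linear_discriminant",
                                        "quadratic_discriminant"),
                           cv_folds = 10,
                           n_match = c(male = 20, female = 26),
                           n_mismatch = c(male = 130, female = 130),
                           measurement_csv = NULL,
                           rtem_threshold = 7.5, alpha = 0.05) {
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  .assert(cv_folds >= 2, "cv_folds must be at least 2")
  list(seed = as.integer(seed), out_dir = out_dir,
       n_individuals = n_individuals, families = families,
       cv_folds = cv_folds, n_match = n_match, n_mismatch = n_mismatch,
       measurement_csv = measurement_csv,
       rtem_threshold = rtem_threshold, alpha = alpha)
}

#' Run the full two-arm screening pipeline
#'
#' Osteometric arm: simulate (or read) a measurement population, build the
#' exhaustive pairwise dataset, evaluate the configured classifier families
#' and the correspondent-measurement correlations. Screening arm: simulate
#' calibrated RMS outcomes, derive the exclusion threshold and summarise
#' verdicts and group statistics. Writes `measurements.csv`,
#' `classifier_metrics.csv`, `correlation_report.csv`, `screening.json` and
#' `provenance.json` into `config$out_dir`.
#'
#' @param config List from [default_config()], or a path to a JSON file with
#'   the same fields.
#' @return Invisibly, a list with `measurements`, `pairs`, `metrics`,
#'   `correlations`, `screening` and `paths`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    .assert(file.exists(config), sprintf("config file not found: %s", config))
    config <- utils::modifyList(default_config(),
                                jsonlite::read_json(config, simplifyVector = TRUE))
  }
  .assert(is.list(config) && !is.null(config$seed), "invalid configuration")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    measurements = file.path(config$out_dir, "measurements.csv"),
    metrics = file.path(config$out_dir, "classifier_metrics.csv"),
    correlations = file.path(config$out_dir, "correlation_report.csv"),
    screening = file.path(config$out_dir, "screening.json"),
    provenance = file.path(config$out_dir, "provenance.json"))

  measurements <- if (!is.null(config$measurement_csv)) {
    read_measurement_csv(config$measurement_csv)
  } else {
    simulate_measurements(config$n_individuals, seed = config$seed)
  }
  write_measurement_csv(measurements, paths$measurements)

  pairs <- build_pairwise_dataset(measurements)
  metrics <- evaluate_classifiers(pairs, families = config$families,
                                  k = config$cv_folds, seed = config$seed)
  write_report_csv(metrics, paths$metrics)
  correlations <- correlation_report(measurements)
  write_report_csv(correlations, paths$correlations)

  n_match <- config$n_match; n_mismatch <- config$n_mismatch
  if (is.list(n_match)) n_match <- unlist(n_match)
  if (is.list(n_mismatch)) n_mismatch <- unlist(n_mismatch)
  rms <- simulate_rms(n_match, n_mismatch, seed = config$seed + 1L)
  scr_df <- data.frame(rms = rms$rms, label = as.character(rms$group),
                       stringsAsFactors = FALSE)
  if ("sex" %in% names(rms)) scr_df$sex <- rms$sex
  screening <- summarize_screening(scr_df, alpha = config$alpha)
  jsonlite::write_json(list(
    threshold_mm = screening$threshold,
    exclusion_fraction_mismatch = screening$exclusion_fraction_mismatch,
    excluded_matches = screening$excluded_matches,
    anova = screening$group_stats$anova,
    levene = screening$group_stats$levene,
    normality = screening$group_stats$normality,
    verdicts = screening$verdicts),
    paths$screening, auto_unbox = TRUE, digits = NA, na = "null")

  jsonlite::write_json(list(
    package = "craniosort",
    version = as.character(utils::packageVersion("craniosort")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    n_individuals = nrow(measurements),
    families = config$families,
    cv_folds = config$cv_folds,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paths$provenance, auto_unbox = TRUE)

  invisible(list(measurements = measurements, pairs = pairs, metrics = metrics,
                 correlations = correlations, screening = screening,
                 paths = paths))
}
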