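# Osteometric data model: 16 linear distances (mm) of the atlanto-occipital
# joint region, measurement reliability (TEM), difference features and the
# exhaustive cranium x atlas pairwise dataset.

# Column order of the measurement schema (occipital side then atlas side).
.OC_NAMES <- c("AR_OC", "AL_OC", "CR_OC", "CL_OC", "E_OC", "G_OC", "K_OC", "I_OC")
.C1_NAMES <- c("BRS_C1", "BLS_C1", "DRS_C1", "DLS_C1", "F_C1", "H_C1", "J_C1", "L_C1")

# Mechanically corresponding measurement pairs, in feature order f1..f8.
# Note I_OC (lateral span) pairs with J_C1 (lateral span) and K_OC (medial
# separation) with L_C1 (medial separation), so the pairing is by anatomical
# homology, not by schema position.
.PAIR_OC <- c("AR_OC", "AL_OC", "CR_OC", "CL_OC", "E_OC", "G_OC", "I_OC", "K_OC")
.PAIR_C1 <- c("BRS_C1", "BLS_C1", "DRS_C1", "DLS_C1", "F_C1", "H_C1", "J_C1", "L_C1")

.SEX_LEVELS <- c("female", "male", "unknown")

#' Measurement table schema
#'
#' Column names, in canonical order, of a cranium-atlas measurement table:
#' an identifier, a sex label (`female`/`male`/`unknown`) and the sixteen
#' linear distances in millimetres (eight occipital, eight atlas).
#'
#' @return Character vector of 18 column names.
#' @export
#' @examples
#' measurement_schema()
measurement_schema <- function() {
  c("individual_id", "sex", .OC_NAMES, .C1_NAMES)
}

#' Corresponding measurement pairs
#'
#' The eight mechanically corresponding occipital/atlas measurement pairs, in
#' the order used for features `f1`..`f8`.
#'
#' @return Data frame with columns `feature`, `oc`, `c1`.
#' @export
measurement_pairings <- function() {
  data.frame(feature = paste0("f", 1:8), oc = .PAIR_OC, c1 = .PAIR_C1,
             stringsAsFactors = FALSE)
}

#' Validate a measurement table
#'
#' Checks that a data frame follows the [measurement_schema()]: all sixteen
#' measurement columns present, strictly positive and finite, identifiers
#' unique, sex labels in `female`/`male`/`unknown`.
#'
#' @param x Data frame with (at least) the schema columns.
#' @return `x` with columns in canonical order and class `measurement_table`.
#' @export
as_measurement_table <- function(x) {
  .assert(is.data.frame(x), "measurement table must be a data frame")
  schema <- measurement_schema()
  missing_cols <- setdiff(schema, names(x))
  .assert(length(missing_cols) == 0,
          paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  x <- x[, schema]
  x$individual_id <- as.character(x$individual_id)
  x$sex <- as.character(x$sex)
  .assert(!anyDuplicated(x$individual_id), "individual_id values must be unique")
  .assert(all(x$sex %in% .SEX_LEVELS),
          "sex must be one of 'female', 'male', 'unknown'")
  for (nm in c(.OC_NAMES, .C1_NAMES)) {
    v <- x[[nm]]
    .assert(is.numeric(v), sprintf("column %s must be numeric", nm))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0)
      stop(sprintf("column %s: non-positive or non-finite value at row %d",
                   nm, bad[1]), call. = FALSE)
  }
  class(x) <- unique(c("measurement_table", class(x)))
  x
}

#' Technical error of measurement (TEM)
#'
#' Agreement between two series of repeated measurements, using the Dahlberg
#' absolute TEM `sqrt(sum(d^2) / (2N))` and the relative TEM expressed as a
#' percentage of the grand mean of all `2N` values. Repeatability is deemed
#' acceptable when rTEM does not exceed `acceptability_threshold` (default
#' 7.5%, the conventional anthropometric cut-off).
#'
#' @param series_a,series_b Numeric vectors of equal length: the repeated
#'   measurements (mm), paired element-wise.
#' @param acceptability_threshold Maximum acceptable rTEM, in percent.
#' @return An object of class `tem_result`: list with `tem` (mm), `rtem` (%),
#'   `acceptable`, `threshold` and `n`.
#' @export
#' @examples
#' compute_tem(c(10.0, 20.0), c(10.2, 19.8))
compute_tem <- function(series_a, series_b, acceptability_threshold = 7.5) {
  .assert(is.numeric(series_a) && is.numeric(series_b),
          "measurement series must be numeric")
  .assert(length(series_a) == length(series_b),
          "measurement series must have equal length")
  .assert(length(series_a) >= 1, "measurement series must be non-empty")
  .assert(all(is.finite(series_a)) && all(is.finite(series_b)),
          "measurement series must be finite")
  .assert(all(series_a > 0) && all(series_b > 0),
          "measurement values must be strictly positive")
  n <- length(series_a)
  d <- series_a - series_b
  tem <- sqrt(sum(d^2) / (2 * n))
  rtem <- 100 * tem / mean(c(series_a, series_b))
  out <- list(tem = tem, rtem = rtem,
              acceptable = rtem <= acceptability_threshold,
              threshold = acceptability_threshold, n = n)
  class(out) <- "tem_result"
  out
}

#' @export
print.tem_result <- function(x, ...) {
  cat(sprintf("TEM: %.4f mm  rTEM: %.3f%%  (%s at %.1f%%; N = %d)\n",
              x$tem, x$rtem, if (x$acceptable) "acceptable" else "not acceptable",
              x$threshold, x$n))
  invisible(x)
}

.side_vector <- function(x, names) {
  if (is.data.frame(x)) {
    .assert(nrow(x) == 1, "expected a single individual (one row)")
    x <- unlist(x[, intersect(names(x), names), drop = FALSE])
  }
  .assert(is.numeric(x), "measurements must be numeric")
  .assert(all(names %in% names(x)),
          paste0("missing measurement(s): ",
                 paste(setdiff(names, names(x)), collapse = ", ")))
  v <- x[names]
  .assert(all(is.finite(v)), "measurements must be finite")
  v
}

.measurement_norm <- function(v, squared = FALSE) {
  if (squared) sum(v^2) else sqrt(sum(v^2))
}

#' Extract the nine pairwise difference features
#'
#' For the eight corresponding measurement pairs the feature is the occipital
#' value minus the atlas value (in mm); the ninth feature is the difference
#' of the Euclidean norms of the two 8-measurement vectors. Direction follows
#' the convention under which corresponding-pair feature means are negative
#' for the facet widths and foramen diameters (the atlas facet is on average
#' the larger of the two).
#'
#' @param oc Occipital-side measurements: named numeric vector (names from
#'   the schema) or one row of a [as_measurement_table()] table.
#' @param c1 Atlas-side measurements, likewise.
#' @param squared_norm If `TRUE`, use the squared norm `sum(v^2)` for `f9`
#'   instead of the Euclidean norm (non-standard; off by default).
#' @return Named numeric vector `f1`..`f9` (mm).
#' @export
extract_features <- function(oc, c1, squared_norm = FALSE) {
  oc <- .side_vector(oc, .OC_NAMES)
  c1 <- .side_vector(c1, .C1_NAMES)
  f <- unname(oc[.PAIR_OC] - c1[.PAIR_C1])
  f9 <- .measurement_norm(oc, squared_norm) - .measurement_norm(c1, squared_norm)
  stats::setNames(c(f, f9), paste0("f", 1:9))
}

#' Build the exhaustive cranium x atlas pairwise dataset
#'
#' Combines every individual's occipital measurements with every individual's
#' atlas measurements, yielding `n^2` feature rows of which exactly `n` (the
#' diagonal) are labelled `correspondent`. This is the working dataset for the
#' pairwise classifiers; with 150 individuals it has 22,500 rows.
#'
#' @param individuals A [as_measurement_table()]-compatible data frame.
#' @param squared_norm Passed to [extract_features()].
#' @return Data frame (class `pair_dataset`) with columns `oc_id`, `c1_id`,
#'   `f1`..`f9` and `label` (factor, levels `non-correspondent`,
#'   `correspondent`).
#' @export
build_pairwise_dataset <- function(individuals, squared_norm = FALSE) {
  tbl <- as_measurement_table(individuals)
  n <- nrow(tbl)
  .assert(n >= 1, "need at least one individual")
  oc_mat <- as.matrix(tbl[, .PAIR_OC])
  c1_mat <- as.matrix(tbl[, .PAIR_C1])
  oc_i <- rep(seq_len(n), each = n)
  c1_i <- rep(seq_len(n), times = n)
  feats <- oc_mat[oc_i, , drop = FALSE] - c1_mat[c1_i, , drop = FALSE]
  norm_fun <- if (squared_norm) function(m) rowSums(m^2) else
    function(m) sqrt(rowSums(m^2))
  f9 <- norm_fun(oc_mat)[oc_i] - norm_fun(c1_mat)[c1_i]
  out <- data.frame(oc_id = tbl$individual_id[oc_i],
                    c1_id = tbl$individual_id[c1_i],
                    stringsAsFactors = FALSE)
  colnames(feats) <- paste0("f", 1:8)
  out <- cbind(out, as.data.frame(feats), f9 = f9)
  out$label <- factor(ifelse(out$oc_id == out$c1_id,
                             "correspondent", "non-correspondent"),
                      levels = c("non-correspondent", "correspondent"))
  rownames(out) <- NULL
  class(out) <- unique(c("pair_dataset", class(out)))
  out
}
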