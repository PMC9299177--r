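# Match/mismatch superimposition experiment design, the max-of-matches
# exclusion threshold, per-pair verdicts and group statistics.

#' Design the match/mismatch superimposition experiment
#'
#' Every individual contributes one match pair (its own cranium and atlas);
#' mismatch pairs are ordered same-sex cranium/atlas combinations sampled
#' uniformly without replacement within each sex. The reference design -- 46
#' individuals (26 female, 20 male) with 130 mismatches per sex -- yields 306
#' superimposition tasks.
#'
#' @param individuals Data frame with columns `individual_id` and `sex`
#'   (e.g. a measurement table), or a character vector of ids together with
#'   `sex` as a separate vector.
#' @param n_mismatch_per_sex Number of mismatch pairs to draw per sex.
#' @param sex Optional vector of sex labels when `individuals` is a plain
#'   id vector.
#' @param seed Integer seed for the mismatch sampling.
#' @return Object of class `experiment_design`: list with `match_pairs`
#'   (data frame `oc_id`, `c1_id`, `sex`), `mismatch_pairs` (same columns)
#'   and `seed`.
#' @export
design_experiment <- function(individuals, n_mismatch_per_sex, sex = NULL,
                              seed = 1L) {
  if (is.data.frame(individuals)) {
    .assert(all(c("individual_id", "sex") %in% names(individuals)),
            "individuals must have columns individual_id and sex")
    ids <- as.character(individuals$individual_id)
    sex <- as.character(individuals$sex)
  } else {
    ids <- as.character(individuals)
    .assert(!is.null(sex) && length(sex) == length(ids),
            "sex labels must accompany the id vector")
    sex <- as.character(sex)
  }
  .assert(!anyDuplicated(ids), "individual ids must be unique")
  .assert(n_mismatch_per_sex >= 0, "n_mismatch_per_sex must be non-negative")
  match_pairs <- data.frame(oc_id = ids, c1_id = ids, sex = sex,
                            stringsAsFactors = FALSE)
  mismatch <- list()
  for (s in intersect(c("female", "male"), unique(sex))) {
    sids <- ids[sex == s]
    ns <- length(sids)
    avail <- ns * (ns - 1)
    .assert(n_mismatch_per_sex <= avail,
            sprintf("requested %d mismatch pairs for sex '%s' but only %d ordered pairs exist",
                    n_mismatch_per_sex, s, avail))
    if (n_mismatch_per_sex == 0 || avail == 0) next
    oc_i <- rep(seq_len(ns), each = ns)
    c1_i <- rep(seq_len(ns), times = ns)
    keep <- oc_i != c1_i
    oc_i <- oc_i[keep]; c1_i <- c1_i[keep]
    pick <- with_seed(seed + match(s, c("female", "male")),
                      sample(avail, n_mismatch_per_sex))
    mismatch[[s]] <- data.frame(oc_id = sids[oc_i[pick]],
                                c1_id = sids[c1_i[pick]], sex = s,
                                stringsAsFactors = FALSE)
  }
  mismatch_pairs <- if (length(mismatch) > 0) do.call(rbind, mismatch)
                    else data.frame(oc_id = character(), c1_id = character(),
                                    sex = character(), stringsAsFactors = FALSE)
  rownames(mismatch_pairs) <- NULL
  structure(list(match_pairs = match_pairs, mismatch_pairs = mismatch_pairs,
                 seed = seed),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("experiment_design: %d match + %d mismatch = %d superimposition tasks (seed %d)\n",
              nrow(x$match_pairs), nrow(x$mismatch_pairs),
              nrow(x$match_pairs) + nrow(x$mismatch_pairs), x$seed))
  invisible(x)
}

.rms_values <- function(x) {
  if (is.numeric(x)) return(x)
  if (inherits(x, "distance_summary")) return(x$rms)
  if (inherits(x, "superimposition")) return(x$summary$rms)
  if (is.list(x)) return(vapply(x, .rms_values, numeric(1)))
  stop("cannot extract RMS values from this object", call. = FALSE)
}

#' Derive the exclusion threshold from match superimpositions
#'
#' The screening threshold is the maximum RMS observed among superimpositions
#' of bones known to belong to the same individual: above it, only
#' non-corresponding pairs were ever observed.
#'
#' @param match_summaries Numeric RMS values (mm), or a list of
#'   [distance_summary()]/`superimposition` objects.
#' @return The threshold (mm).
#' @export
#' @examples
#' derive_threshold(c(0.20, 0.29, 0.53))
derive_threshold <- function(match_summaries) {
  v <- .rms_values(match_summaries)
  .assert(length(v) >= 1, "need at least one match summary")
  .assert(all(is.finite(v)) && all(v >= 0), "RMS values must be non-negative")
  max(v)
}

#' Screen one candidate pair against the exclusion threshold
#'
#' Exclusion-only semantics: an RMS strictly above the threshold excludes the
#' pair; anything at or below it is *inconclusive* -- a low RMS never
#' positively establishes that two bones belong to the same individual.
#'
#' @param rms RMS value(s) in mm.
#' @param threshold Exclusion threshold in mm (> 0).
#' @return Character vector: `"excluded"` or `"inconclusive"`.
#' @export
#' @examples
#' screen_pair(c(0.94, 0.20), threshold = 0.53)
screen_pair <- function(rms, threshold) {
  .assert(is.numeric(rms) && all(is.finite(rms)), "rms must be finite numeric")
  .assert(all(rms >= 0), "rms must be non-negative")
  .assert(is.numeric(threshold) && length(threshold) == 1 && threshold > 0,
          "threshold must be a single positive value")
  ifelse(rms > threshold, "excluded", "inconclusive")
}

#' Summarise a screening experiment
#'
#' Derives (or takes) the exclusion threshold, assigns per-pair verdicts and
#' computes the mismatch exclusion fraction, plus group statistics when sex
#' labels are available.
#'
#' @param results Data frame with columns `rms` (mm) and `label`
#'   (`"match"`/`"mismatch"`), optionally `oc_id`, `c1_id`, `sex`; or a list
#'   of `superimposition` objects.
#' @param threshold Exclusion threshold (mm); `NULL` (default) derives it
#'   from the match rows via [derive_threshold()].
#' @param alpha Significance level for the group statistics.
#' @return Object of class `screening_result`: list with `threshold`,
#'   `verdicts` (the results frame plus a `verdict` column),
#'   `exclusion_fraction_mismatch`, `excluded_matches` and (when computable)
#'   `group_stats`.
#' @export
summarize_screening <- function(results, threshold = NULL, alpha = 0.05) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(s) {
      .assert(inherits(s, "superimposition"), "list entries must be superimpositions")
      data.frame(oc_id = s$oc_id %||% NA_character_,
                 c1_id = s$c1_id %||% NA_character_,
                 label = s$label, rms = s$summary$rms, stringsAsFactors = FALSE)
    }))
  .assert(is.data.frame(results) && all(c("rms", "label") %in% names(results)),
          "results must contain columns rms and label")
  .assert(all(results$label %in% c("match", "mismatch")),
          "label must be 'match' or 'mismatch'")
  is_match <- results$label == "match"
  if (is.null(threshold)) {
    .assert(any(is_match), "cannot derive a threshold without match results")
    threshold <- derive_threshold(results$rms[is_match])
  }
  results$verdict <- screen_pair(results$rms, threshold)
  n_mis <- sum(!is_match)
  excl_frac <- if (n_mis == 0) NA_real_
               else mean(results$verdict[!is_match] == "excluded")
  if (n_mis == 0)
    warning("no mismatch results: exclusion fraction undefined", call. = FALSE)
  gs <- NULL
  if ("sex" %in% names(results) && !anyNA(results$sex) &&
      any(is_match) && n_mis > 0) {
    gs <- tryCatch(group_stats(results$rms, group = results$label,
                               sex = results$sex, alpha = alpha),
                   error = function(e) NULL)
  }
  structure(list(threshold = threshold, verdicts = results,
                 exclusion_fraction_mismatch = excl_frac,
                 excluded_matches = sum(results$verdict[is_match] == "excluded"),
                 group_stats = gs, alpha = alpha),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening_result: threshold %.4f mm\n", x$threshold))
  n_match <- sum(x$verdicts$label == "match")
  n_mis <- sum(x$verdicts$label == "mismatch")
  cat(sprintf("  %d match, %d mismatch superimpositions\n", n_match, n_mis))
  if (!is.na(x$exclusion_fraction_mismatch))
    cat(sprintf("  mismatches excluded: %.1f%%\n",
                100 * x$exclusion_fraction_mismatch))
  cat(sprintf("  matches excluded: %d (exclusion-only screen: matches are never confirmed)\n",
              x$excluded_matches))
  if (!is.null(x$group_stats)) {
    an <- x$group_stats$anova
    g <- an[an$term == "group", ]
    cat(sprintf("  match vs mismatch: F = %.2f, p = %.3g\n", g$F, g$p))
  }
  invisible(x)
}

#' Scatter plot of RMS values by group
#'
#' @param x A `screening_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.screening_result <- function(x, ...) {
  v <- x$verdicts
  grp <- factor(v$label, levels = c("match", "mismatch"))
  set.seed(0)
  xj <- as.integer(grp) + stats::runif(nrow(v), -0.12, 0.12)
  graphics::plot(xj, v$rms, xaxt = "n", xlab = "", ylab = "RMS (mm)",
                 xlim = c(0.5, 2.5),
                 col = ifelse(v$verdict == "excluded", "firebrick", "grey30"),
                 pch = 19, ...)
  graphics::axis(1, at = 1:2, labels = levels(grp))
  graphics::abline(h = x$threshold, lty = 2, col = "firebrick")
  graphics::mtext(sprintf("threshold %.2f mm", x$threshold), side = 4,
                  at = x$threshold, las = 1, cex = 0.8)
  invisible(x)
}

# Jarque-Bera normality test (skewness/kurtosis based, chi-square with 2 df).
.jarque_bera <- function(x) {
  n <- length(x)
  .assert(n >= 4, "Jarque-Bera test needs at least 4 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  S <- m3 / m2^1.5
  K <- m4 / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Group statistics for RMS values
#'
#' Two-way ANOVA (factors: sex and group, with interaction; type-II sums of
#' squares for the unbalanced design), a Levene test (mean-centred) for
#' homoscedasticity across the sex-by-group cells and a Jarque-Bera normality
#' test per cell. If one factor has an empty cell the model is reduced to a
#' one-way ANOVA on `group` with a warning.
#'
#' @param rms Numeric RMS values (mm).
#' @param group Factor/character: `"match"`/`"mismatch"` per value.
#' @param sex Factor/character sex label per value.
#' @param alpha Significance level (reported, not enforced).
#' @return List with `anova` (data frame `term`, `F`, `p`), `levene`
#'   (list `F`, `p`), `normality` (data frame per cell: `cell`, `n`,
#'   `statistic`, `p`) and `alpha`.
#' @export
group_stats <- function(rms, group, sex, alpha = 0.05) {
  .assert(is.numeric(rms) && all(is.finite(rms)), "rms must be finite numeric")
  group <- factor(group)
  sex <- factor(sex)
  .assert(length(group) == length(rms) && length(sex) == length(rms),
          "rms, group and sex must have equal length")
  df <- data.frame(rms = rms, group = group, sex = sex)
  cells <- table(df$sex, df$group)
  two_way <- nlevels(df$sex) >= 2 && nlevels(df$group) >= 2 && all(cells >= 2)
  if (two_way) {
    fit <- stats::lm(rms ~ sex * group, data = df)
    an <- car::Anova(fit, type = 2)
    terms <- c("sex", "group", "sex:group")
    anova_tab <- data.frame(term = terms,
                            F = an[terms, "F value"],
                            p = an[terms, "Pr(>F)"],
                            stringsAsFactors = FALSE)
    lev <- car::leveneTest(rms ~ sex * group, data = df, center = mean)
    cell_lab <- interaction(df$sex, df$group, sep = ":")
  } else {
    warning("empty or near-empty sex-by-group cell: reduced to one-way ANOVA on group",
            call. = FALSE)
    .assert(nlevels(droplevels(df$group)) >= 2, "need two groups for an ANOVA")
    fit <- stats::lm(rms ~ group, data = df)
    an <- stats::anova(fit)
    anova_tab <- data.frame(term = "group", F = an["group", "F value"],
                            p = an["group", "Pr(>F)"], stringsAsFactors = FALSE)
    lev <- car::leveneTest(rms ~ group, data = df, center = mean)
    cell_lab <- df$group
  }
  normality <- do.call(rbind, lapply(levels(droplevels(factor(cell_lab))), function(cl) {
    x <- df$rms[cell_lab == cl]
    jb <- if (length(x) >= 4) .jarque_bera(x)
          else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(cell = cl, n = length(x), statistic = jb$statistic,
               p = jb$p_value, stringsAsFactors = FALSE)
  }))
  list(anova = anova_tab,
       levene = list(F = lev[1, "F value"], p = lev[1, "Pr(>F)"]),
       normality = normality, alpha = alpha)
}
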