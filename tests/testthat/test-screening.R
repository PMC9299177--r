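# Experiment design, threshold derivation, verdicts and group statistics.

test_that("experiment design reproduces the reference task counts", {
  ids <- sprintf("i%02d", 1:46)
  sex <- rep(c("female", "male"), c(26, 20))
  d <- design_experiment(ids, 130, sex = sex, seed = 1)
  expect_equal(nrow(d$match_pairs), 46)
  expect_equal(nrow(d$mismatch_pairs), 260)
  expect_equal(sum(d$mismatch_pairs$sex == "female"), 130)
  expect_equal(sum(d$mismatch_pairs$sex == "male"), 130)
  # mismatch pairs: ordered, same-sex, no self-pairs, no duplicates
  expect_true(all(d$mismatch_pairs$oc_id != d$mismatch_pairs$c1_id))
  expect_false(anyDuplicated(paste(d$mismatch_pairs$oc_id,
                                   d$mismatch_pairs$c1_id)) > 0)
  sex_of <- setNames(sex, ids)
  expect_true(all(sex_of[d$mismatch_pairs$oc_id] ==
                  sex_of[d$mismatch_pairs$c1_id]))
  # reproducible
  d2 <- design_experiment(ids, 130, sex = sex, seed = 1)
  expect_identical(d$mismatch_pairs, d2$mismatch_pairs)
})

test_that("experiment design is exhaustive at the counting bound and errors past it", {
  d <- design_experiment(c("a", "b", "c"), 6, sex = rep("male", 3), seed = 2)
  expect_equal(nrow(d$match_pairs), 3)
  expect_equal(nrow(d$mismatch_pairs), 6)
  expect_setequal(paste(d$mismatch_pairs$oc_id, d$mismatch_pairs$c1_id),
                  c("a b", "a c", "b a", "b c", "c a", "c b"))
  expect_error(design_experiment(sprintf("m%02d", 1:20), 381,
                                 sex = rep("male", 20), seed = 1),
               "380")
})

test_that("threshold is the maximum match RMS, order-invariant", {
  expect_equal(derive_threshold(c(0.20, 0.29, 0.53)), 0.53)
  expect_equal(derive_threshold(c(0.53, 0.20, 0.29)), 0.53)
  expect_equal(derive_threshold(0.31), 0.31)
  expect_error(derive_threshold(numeric(0)), "at least one")
})

test_that("screening verdicts are exclusion-only with a strict threshold", {
  expect_equal(screen_pair(0.94, 0.53), "excluded")
  expect_equal(screen_pair(0.20, 0.53), "inconclusive")
  expect_equal(screen_pair(0.53, 0.53), "inconclusive")  # tie is conservative
  expect_equal(screen_pair(c(0, 10), 0.53), c("inconclusive", "excluded"))
  expect_error(screen_pair(-0.1, 0.53), "non-negative")
  # no verdict value ever asserts a positive match
  craniosort:::with_seed(31, {
    v <- screen_pair(runif(100, 0, 2), 0.53)
    expect_true(all(v %in% c("excluded", "inconclusive")))
  })
})

test_that("exclusion fraction spans 0 to 1 and matches are never excluded by construction", {
  df_lo <- data.frame(rms = c(0.3, 0.4, 0.1, 0.2),
                      label = c("match", "match", "mismatch", "mismatch"))
  s_lo <- summarize_screening(df_lo)
  expect_equal(s_lo$exclusion_fraction_mismatch, 0)
  df_hi <- data.frame(rms = c(0.3, 0.4, 2.1, 3.2),
                      label = c("match", "match", "mismatch", "mismatch"))
  s_hi <- summarize_screening(df_hi)
  expect_equal(s_hi$exclusion_fraction_mismatch, 1)
  expect_equal(s_hi$threshold, 0.4)
  expect_equal(s_hi$excluded_matches, 0)
  expect_warning(
    s_na <- summarize_screening(data.frame(rms = 0.2, label = "match")),
    "no mismatch")
  expect_true(is.na(s_na$exclusion_fraction_mismatch))
})

test_that("threshold monotonicity: larger matches never shrink the threshold, higher thresholds never exclude more", {
  craniosort:::with_seed(32, {
    base <- runif(10, 0.1, 0.5)
    thr <- derive_threshold(base)
    expect_gte(derive_threshold(c(base, thr + 0.2)), thr)
    mis <- runif(50, 0, 2)
    f <- function(t) mean(screen_pair(mis, t) == "excluded")
    ts <- sort(runif(8, 0.1, 1.5))
    expect_true(all(diff(sapply(ts, f)) <= 0))
  })
})

test_that("two-way ANOVA matches hand-computed sums of squares on a balanced design", {
  # 2 x 2 balanced, 2 observations per cell (type II == classical)
  rms <- c(1, 2, 3, 4, 2, 3, 6, 7)
  sex <- rep(c("female", "male"), each = 4)
  grp <- rep(c("match", "mismatch", "match", "mismatch"), each = 2)
  gm <- mean(rms)
  ss <- function(idx) {
    # factor sum of squares from level means
    lv <- split(rms, idx)
    sum(vapply(lv, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  }
  ss_sex <- ss(sex); ss_grp <- ss(grp)
  cellm <- tapply(rms, list(sex, grp), mean)
  ss_cells <- 2 * sum((cellm - gm)^2)
  ss_int <- ss_cells - ss_sex - ss_grp
  # residuals: subtract each observation's cell mean
  ss_res <- sum((rms - ave(rms, interaction(sex, grp)))^2)
  gs <- suppressWarnings(group_stats(rms, grp, sex))
  f_expect <- c(ss_sex, ss_grp, ss_int) / (ss_res / 4)
  got <- gs$anova
  expect_equal(got$F[got$term == "sex"], f_expect[1], tolerance = 1e-9)
  expect_equal(got$F[got$term == "group"], f_expect[2], tolerance = 1e-9)
  expect_equal(got$F[got$term == "sex:group"], f_expect[3], tolerance = 1e-9)
  expect_equal(got$p[got$term == "group"],
               pf(f_expect[2], 1, 4, lower.tail = FALSE), tolerance = 1e-9)
})

test_that("equal group means give a group F statistic of zero", {
  rms <- c(1, 3, 1, 3, 2, 2, 2.5, 1.5)
  grp <- rep(c("match", "mismatch"), each = 4)
  sex <- rep(c("female", "female", "male", "male"), 2)
  gs <- suppressWarnings(group_stats(rms, grp, sex))
  expect_equal(gs$anova$F[gs$anova$term == "group"], 0, tolerance = 1e-9)
})

test_that("an empty cell degrades to a one-way ANOVA with a warning", {
  rms <- c(1, 2, 3, 2.5, 3.5, 4.5)
  grp <- rep(c("match", "mismatch"), each = 3)
  sex <- c("female", "female", "female", "male", "male", "male")
  expect_warning(gs <- group_stats(rms, grp, sex), "one-way")
  expect_equal(gs$anova$term, "group")
})

test_that("the Jarque-Bera statistic follows its closed form", {
  craniosort:::with_seed(33, {
    x <- rnorm(200)
    jb <- craniosort:::.jarque_bera(x)
    m <- mean(x)
    s2 <- mean((x - m)^2)
    S <- mean((x - m)^3) / s2^1.5
    K <- mean((x - m)^4) / s2^2
    expect_equal(jb$statistic, 200 / 6 * (S^2 + (K - 3)^2 / 4))
    expect_gt(jb$p_value, 0.01)  # normal sample rarely rejected
    y <- rexp(200)               # skewed sample strongly rejected
    expect_lt(craniosort:::.jarque_bera(y)$p_value, 1e-4)
  })
})

test_that("match/mismatch group separation is detected with high power under calibration", {
  hits <- craniosort:::with_seed(34, {
    replicate(200, {
      r <- simulate_rms(n_match = c(male = 20, female = 26),
                        n_mismatch = c(male = 130, female = 130),
                        seed = sample.int(.Machine$integer.max, 1))
      gs <- group_stats(r$rms, group = as.character(r$group), sex = r$sex)
      gs$anova$p[gs$anova$term == "group"] < 0.05
    })
  })
  expect_gte(mean(hits), 0.95)
})
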