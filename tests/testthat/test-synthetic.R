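# Calibration and determinism of the three synthetic generators, and the
# end-to-end mesh pipeline property.

test_that("measurement generator handles n = 0 and is seed-deterministic", {
  empty <- simulate_measurements(0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "measurement_table")
  a <- simulate_measurements(25, seed = 7)
  b <- simulate_measurements(25, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_measurements(25, seed = 8)))
})

test_that("measurement generator recovers its calibration at large n", {
  tbl <- simulate_measurements(5000, seed = 42)
  p <- measurement_params()
  expect_equal(mean(tbl$AR_OC), unname(p$oc_mean["AR_OC"]), tolerance = 0.1 / 10.5)
  expect_equal(sd(tbl$AR_OC), unname(p$oc_sd["AR_OC"]), tolerance = 0.05)
  expect_equal(cor(tbl$AR_OC, tbl$BRS_C1), p$r[1], tolerance = 0.05 / 0.514)
  expect_equal(cor(tbl$I_OC, tbl$J_C1), p$r[7], tolerance = 0.05 / 0.606)
  # shared size factor induces positive cross-measurement correlation
  expect_gt(cor(tbl$CR_OC, tbl$E_OC), 0.1)
})

test_that("population means at n = 150 stay within two standard errors of target", {
  p <- measurement_params()
  targets <- c(p$oc_mean, p$c1_mean)
  sds <- c(p$oc_sd, p$c1_sd)
  cols <- names(targets)
  inside <- craniosort:::with_seed(43, {
    sapply(1:40, function(i) {
      tbl <- simulate_measurements(150, seed = sample.int(1e6, 1))
      means <- colMeans(as.matrix(tbl[, cols]))
      abs(means - targets) <= 2 * sds / sqrt(150)
    })
  })
  expect_gte(mean(inside), 0.90)
})

test_that("RMS generator respects its bounds exactly and matches moments at large n", {
  p <- rms_params()
  big <- simulate_rms(n_match = 10000, n_mismatch = 10000, seed = 5)
  m <- big$rms[big$group == "match"]
  mm <- big$rms[big$group == "mismatch"]
  expect_true(all(m >= p$match$total["lower"] & m <= p$match$total["upper"]))
  expect_true(all(mm >= p$mismatch$total["lower"] & mm <= p$mismatch$total["upper"]))
  expect_equal(mean(mm), 0.46, tolerance = 0.01 / 0.46)
  expect_equal(sd(mm), 0.20, tolerance = 0.01 / 0.20)
  expect_equal(mean(m), 0.29, tolerance = 0.01 / 0.29)
  expect_equal(sd(m), 0.09, tolerance = 0.01 / 0.09)
})

test_that("match draws never exceed the 0.53 mm calibration ceiling", {
  maxima <- craniosort:::with_seed(44, {
    sapply(1:50, function(i)
      max(simulate_rms(46, 0, seed = sample.int(1e6, 1))$rms))
  })
  expect_true(all(maxima <= 0.53))
})

test_that("RMS generator is deterministic and validates parameters", {
  a <- simulate_rms(10, 10, seed = 3)
  expect_identical(a, simulate_rms(10, 10, seed = 3))
  bad <- rms_params()
  bad$match$total["mean"] <- 0.60  # outside [0.15, 0.53]
  expect_error(simulate_rms(5, 0, params = bad), "inside the bounds")
  bad2 <- rms_params()
  bad2$match$total["sd"] <- 0.30   # sd^2 > (mean-lo)(hi-mean)
  expect_error(simulate_rms(5, 0, params = bad2), "infeasible")
  expect_error(simulate_rms(-1, 0), "non-negative")
})

test_that("both truncated families are supported", {
  for (fam in c("truncated_lognormal", "truncated_normal")) {
    r <- simulate_rms(2000, 2000, params = rms_params(family = fam), seed = 9)
    mm <- r$rms[r$group == "mismatch"]
    expect_equal(mean(mm), 0.46, tolerance = 0.03)
    expect_true(all(mm >= 0.14 & mm <= 1.49))
  }
})

test_that("surface pairs are bitwise-deterministic in their seeds", {
  a <- simulate_surface_pair(123, matched = FALSE)
  b <- simulate_surface_pair(123, matched = FALSE)
  expect_identical(a, b)
  expect_false(identical(a$c1, simulate_surface_pair(123, matched = TRUE)$c1))
})

test_that("a perfectly congruent pair registers to numerically zero RMS", {
  sp <- simulate_surface_pair(7, params = surface_params(sigma_c = 0,
                                                         rings = 4, sectors = 10))
  s <- superimpose(sp$oc, sp$c1, sp$oc_landmarks, sp$c1_landmarks)
  expect_lt(s$summary$rms, 1e-6)
})

test_that("matched pairs register closer than mismatched pairs", {
  params <- surface_params(rings = 4, sectors = 10)
  res <- craniosort:::with_seed(45, {
    sapply(1:20, function(i) {
      seed <- sample.int(1e6, 1)
      reg <- function(matched) {
        sp <- simulate_surface_pair(seed, matched = matched, params = params,
                                    partner_seed = seed + 500000L)
        superimpose(sp$oc, sp$c1, sp$oc_landmarks, sp$c1_landmarks)$summary$rms
      }
      c(match = reg(TRUE), mismatch = reg(FALSE))
    })
  })
  expect_lt(median(res["match", ]), median(res["mismatch", ]))
  expect_gte(mean(res["match", ] < res["mismatch", ]), 0.95)
})

test_that("the end-to-end mesh pipeline excludes mismatches but never matches", {
  params <- surface_params(rings = 4, sectors = 10)
  for (run_seed in c(101L, 202L)) {
    sups <- craniosort:::with_seed(run_seed, {
      seeds <- sample.int(1e6, 18)
      lapply(seq_along(seeds), function(i) {
        matched <- i <= 6
        sp <- simulate_surface_pair(seeds[i], matched = matched, params = params,
                                    partner_seed = seeds[i] + 500000L)
        superimpose(sp$oc, sp$c1, sp$oc_landmarks, sp$c1_landmarks,
                    oc_id = sp$oc_id, c1_id = sp$c1_id)
      })
    })
    scr <- summarize_screening(sups)
    expect_equal(scr$excluded_matches, 0)
    expect_gt(scr$exclusion_fraction_mismatch, 0)
  }
})

test_that("surface generator rejects degenerate resolutions", {
  expect_error(surface_params(rings = 1), "resolution")
  expect_error(surface_params(sigma_c = -1), "non-negative")
})
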