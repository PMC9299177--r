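# Calibrated synthetic generators: linear-measurement populations,
# superimposition RMS outcomes, and full articular-surface mesh pairs.

#' Default calibration of the measurement generator
#'
#' Per-measurement means and SDs (mm) and per-pairing target Pearson
#' correlations of the reference population, in pairing order
#' ([measurement_pairings()]).
#'
#' @param p_female Probability that a simulated individual is female
#'   (default 67/150, the reference sample's sex ratio).
#' @return List of generator parameters for [simulate_measurements()].
#' @export
measurement_params <- function(p_female = 67 / 150) {
  list(
    oc_mean = stats::setNames(c(10.5, 10.9, 22.6, 22.6, 31.0, 28.8, 50.5, 16.0), .PAIR_OC),
    oc_sd   = stats::setNames(c(1.3, 1.3, 2.3, 2.3, 2.8, 3.4, 4.7, 2.2), .PAIR_OC),
    c1_mean = stats::setNames(c(11.3, 11.2, 23.3, 23.4, 35.4, 30.3, 50.0, 16.0), .PAIR_C1),
    c1_sd   = stats::setNames(c(1.6, 1.6, 2.8, 2.7, 2.8, 2.4, 4.1, 2.1), .PAIR_C1),
    r = c(0.514, 0.481, 0.650, 0.622, 0.671, 0.591, 0.606, 0.402),
    p_female = p_female,
    min_value = 0.1
  )
}

#' Simulate a measurement population
#'
#' Draws `n` individuals whose sixteen linear measurements reproduce the
#' calibrated means and SDs, and whose corresponding occipital/atlas pairs
#' have the calibrated Pearson correlations. For pairing *i* with target
#' correlation `r_i`, both sides share a per-individual standard normal size
#' factor `s`:
#' `m = mu + sd * (sqrt(r_i) * s + sqrt(1 - r_i) * e)`,
#' with independent residuals `e` per side, so that `cor(m_OC, m_C1) = r_i`
#' in expectation and the shared factor induces realistic cross-measurement
#' size correlation. Values below `min_value` mm are resampled.
#'
#' @param n Number of individuals (>= 0).
#' @param params See [measurement_params()].
#' @param seed Integer seed; same seed, same table.
#' @return A [as_measurement_table()] with `n` rows.
#' @export
simulate_measurements <- function(n, params = measurement_params(), seed = 1L) {
  .assert(is.numeric(n) && length(n) == 1 && n >= 0 && n == round(n),
          "n must be a non-negative integer")
  .assert(all(params$oc_sd > 0) && all(params$c1_sd > 0), "SDs must be positive")
  .assert(all(params$r >= 0) && all(params$r < 1), "correlations must be in [0, 1)")
  empty <- data.frame(individual_id = character(), sex = character(),
                      stringsAsFactors = FALSE)
  for (nm in c(.OC_NAMES, .C1_NAMES)) empty[[nm]] <- numeric()
  if (n == 0) {
    class(empty) <- unique(c("measurement_table", class(empty)))
    return(empty)
  }
  with_seed(seed, {
    sex <- sample(c("female", "male"), n, replace = TRUE,
                  prob = c(params$p_female, 1 - params$p_female))
    s <- stats::rnorm(n)
    draw_side <- function(mu, sdv, ri) {
      x <- mu + sdv * (sqrt(ri) * s + sqrt(1 - ri) * stats::rnorm(n))
      while (any(bad <- x < params$min_value)) {
        x[bad] <- mu + sdv * (sqrt(ri) * s[bad] +
                                sqrt(1 - ri) * stats::rnorm(sum(bad)))
      }
      x
    }
    oc <- matrix(NA_real_, n, 8, dimnames = list(NULL, .PAIR_OC))
    c1 <- matrix(NA_real_, n, 8, dimnames = list(NULL, .PAIR_C1))
    for (i in seq_len(8)) {
      oc[, i] <- draw_side(params$oc_mean[i], params$oc_sd[i], params$r[i])
      c1[, i] <- draw_side(params$c1_mean[i], params$c1_sd[i], params$r[i])
    }
    out <- data.frame(individual_id = sprintf("ind%03d", seq_len(n)), sex = sex,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(oc[, .OC_NAMES]), as.data.frame(c1[, .C1_NAMES]))
    as_measurement_table(out)
  })
}

# --- RMS generator ----------------------------------------------------------

#' Default calibration of the RMS generator
#'
#' Match and mismatch RMS moments and ranges (mm) of the reference
#' superimposition experiment, total and per sex. The default family is a
#' truncated lognormal (right-skewed, positive), whose parameters are solved
#' numerically so that the *truncated* distribution has the target mean and
#' SD.
#'
#' @param family `"truncated_lognormal"` (default) or `"truncated_normal"`.
#' @return List of generator parameters for [simulate_rms()].
#' @export
rms_params <- function(family = c("truncated_lognormal", "truncated_normal")) {
  row <- function(mean, sd, lower, upper)
    c(mean = mean, sd = sd, lower = lower, upper = upper)
  list(
    family = match.arg(family),
    match = list(total = row(0.29, 0.09, 0.15, 0.53),
                 male = row(0.28, 0.08, 0.16, 0.51),
                 female = row(0.31, 0.11, 0.15, 0.51)),
    mismatch = list(total = row(0.46, 0.20, 0.14, 1.49),
                    male = row(0.51, 0.22, 0.18, 1.49),
                    female = row(0.41, 0.17, 0.14, 1.01))
  )
}

# mean/sd of a lognormal or normal truncated to [lo, hi].
.truncated_moments <- function(family, p1, p2, lo, hi) {
  if (family == "truncated_lognormal") {
    za <- (log(lo) - p1) / p2; zb <- (log(hi) - p1) / p2
    Z <- stats::pnorm(zb) - stats::pnorm(za)
    m1 <- exp(p1 + p2^2 / 2) * (stats::pnorm(zb - p2) - stats::pnorm(za - p2)) / Z
    m2 <- exp(2 * p1 + 2 * p2^2) *
      (stats::pnorm(zb - 2 * p2) - stats::pnorm(za - 2 * p2)) / Z
  } else {
    za <- (lo - p1) / p2; zb <- (hi - p1) / p2
    Z <- stats::pnorm(zb) - stats::pnorm(za)
    ratio <- (stats::dnorm(za) - stats::dnorm(zb)) / Z
    m1 <- p1 + p2 * ratio
    v <- p2^2 * (1 + (za * stats::dnorm(za) - zb * stats::dnorm(zb)) / Z - ratio^2)
    m2 <- v + m1^2
  }
  c(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

# Solve distribution parameters so the truncated moments hit (mean, sd).
# Preference order: exact truncated-moment match where the family can reach
# the target; otherwise match the *untruncated* moments and truncate (the
# realized moments then deviate slightly -- unavoidable when the printed SD
# sits near the ceiling allowed by the printed range). Targets infeasible for
# any distribution on [lower, upper] are an error.
.fit_truncated <- function(family, mean, sd, lower, upper) {
  .assert(lower < upper, "lower bound must be below upper bound")
  .assert(lower >= 0, "RMS bounds must be non-negative")
  .assert(mean > lower && mean < upper, "target mean must lie inside the bounds")
  .assert(sd > 0, "target sd must be positive")
  .assert(sd^2 <= (mean - lower) * (upper - mean),
          "infeasible moment/bound combination: no distribution on [lower, upper] has this mean and sd")
  untruncated <- if (family == "truncated_lognormal") {
    cv2 <- (sd / mean)^2
    c(log(mean) - log1p(cv2) / 2, sqrt(log1p(cv2)))
  } else c(mean, sd)
  obj <- function(p) {
    m <- .truncated_moments(family, p[1], exp(p[2]), lower, upper)
    sum((m - c(mean, sd))^2)
  }
  start <- c(untruncated[1], log(untruncated[2]))
  fit <- stats::optim(start, obj, control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value < 1e-10) {
    list(family = family, p1 = fit$par[1], p2 = exp(fit$par[2]),
         lower = lower, upper = upper, matched = "truncated")
  } else {
    list(family = family, p1 = untruncated[1], p2 = untruncated[2],
         lower = lower, upper = upper, matched = "untruncated")
  }
}

# Inverse-CDF draws from the fitted truncated distribution (bounds exact).
.r_truncated <- function(n, fit) {
  if (n == 0) return(numeric(0))
  if (fit$family == "truncated_lognormal") {
    u <- stats::runif(n, stats::plnorm(fit$lower, fit$p1, fit$p2),
                      stats::plnorm(fit$upper, fit$p1, fit$p2))
    stats::qlnorm(u, fit$p1, fit$p2)
  } else {
    u <- stats::runif(n, stats::pnorm(fit$lower, fit$p1, fit$p2),
                      stats::pnorm(fit$upper, fit$p1, fit$p2))
    stats::qnorm(u, fit$p1, fit$p2)
  }
}

#' Simulate superimposition RMS outcomes
#'
#' Labelled RMS draws from the calibrated match and mismatch distributions.
#' Counts may be single totals (pooled calibration rows) or named vectors
#' `c(male = ..., female = ...)` (sex-specific calibration rows, and a `sex`
#' column in the output). Draws respect the calibrated bounds exactly, so
#' match draws never exceed 0.53 mm under the defaults.
#'
#' @param n_match,n_mismatch Number of match / mismatch draws: a single count
#'   or a named `c(male=, female=)` vector.
#' @param params See [rms_params()].
#' @param seed Integer seed; same seed, same draws.
#' @return Data frame with columns `group` (factor `match`/`mismatch`),
#'   `rms` (mm) and, for sex-specific counts, `sex`.
#' @export
#' @examples
#' simulate_rms(n_match = 46, n_mismatch = 260, seed = 1)
simulate_rms <- function(n_match, n_mismatch, params = rms_params(), seed = 1L) {
  by_sex <- !is.null(names(n_match)) || !is.null(names(n_mismatch))
  check_n <- function(n) {
    .assert(is.numeric(n) && all(n >= 0) && all(n == round(n)),
            "counts must be non-negative integers")
    if (by_sex)
      .assert(!is.null(names(n)) && all(names(n) %in% c("male", "female")),
              "sex-specific counts must be named 'male'/'female'")
  }
  check_n(n_match); check_n(n_mismatch)
  draw_group <- function(group, n) {
    if (!by_sex) {
      cal <- params[[group]]$total
      fit <- .fit_truncated(params$family, cal["mean"], cal["sd"],
                            cal["lower"], cal["upper"])
      data.frame(group = rep(group, n), rms = .r_truncated(n, fit),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(names(n), function(s) {
        cal <- params[[group]][[s]]
        fit <- .fit_truncated(params$family, cal["mean"], cal["sd"],
                              cal["lower"], cal["upper"])
        data.frame(group = rep(group, n[[s]]), sex = rep(s, n[[s]]),
                   rms = .r_truncated(n[[s]], fit), stringsAsFactors = FALSE)
      }))
    }
  }
  with_seed(seed, {
    out <- rbind(draw_group("match", n_match), draw_group("mismatch", n_mismatch))
    out$group <- factor(out$group, levels = c("match", "mismatch"))
    rownames(out) <- NULL
    out
  })
}

# --- surface-pair generator -------------------------------------------------

#' Default calibration of the articular-surface generator
#'
#' Facet size distributions follow the linear-measurement calibration
#' (condyle length ~ N(22.6, 2.3) mm, width ~ N(10.5, 1.3) mm; medial
#' separation ~ N(16.0, 2.2) mm, lateral span ~ N(50.5, 4.7) mm). The
#' congruency noise amplitude `sigma_c` (mm, RMS along the surface normal,
#' applied to the atlas facet) is a free parameter of the surface model, not
#' a population value; its default (0.3 mm) makes simulated match/mismatch
#' RMS distributions resemble the calibrated RMS generator qualitatively.
#'
#' @param sigma_c Congruency noise amplitude (mm).
#' @param rings,sectors Facet mesh resolution: concentric rings and sectors
#'   of the elliptical dome patch (vertices per facet
#'   `= 1 + rings * sectors`).
#' @return List of generator parameters for [simulate_surface_pair()].
#' @export
surface_params <- function(sigma_c = 0.3, rings = 6, sectors = 16) {
  .assert(sigma_c >= 0, "sigma_c must be non-negative")
  .assert(rings >= 2 && sectors >= 3, "resolution too low: need rings >= 2, sectors >= 3")
  list(length_mean = 22.6, length_sd = 2.3,
       width_mean = 10.5, width_sd = 1.3,
       medial_sep_mean = 16.0, medial_sep_sd = 2.2,
       lateral_span_mean = 50.5, lateral_span_sd = 4.7,
       height_ratio_mean = 0.35, height_ratio_sd = 0.02,
       sigma_c = sigma_c, rings = rings, sectors = sectors)
}

# Unit-disk parameter grid of an elliptical dome facet, with triangulation.
.facet_template <- function(rings, sectors) {
  r <- rep(seq_len(rings) / rings, each = sectors)
  th <- rep(2 * pi * (seq_len(sectors) - 1) / sectors, times = rings)
  u <- c(0, r * cos(th))
  v <- c(0, r * sin(th))
  idx <- function(i, j) 1L + (i - 1L) * sectors + ((j - 1L) %% sectors) + 1L
  fan <- do.call(rbind, lapply(seq_len(sectors), function(j)
    c(1L, idx(1L, j), idx(1L, j + 1L))))
  quads <- do.call(rbind, lapply(seq_len(rings - 1), function(i)
    do.call(rbind, lapply(seq_len(sectors), function(j) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      rbind(c(a, b, d), c(a, d, cc))
    }))))
  list(u = u, v = v, faces = rbind(fan, quads),
       boundary = which(c(0, r) > 1 - 1e-12))
}

# Per-individual joint geometry (both facets), drawn deterministically.
.individual_geometry <- function(seed, params) {
  with_seed(seed, {
    draw <- function(mu, sdv, floor) pmax(stats::rnorm(1, mu, sdv), floor)
    list(
      length = c(left = draw(params$length_mean, params$length_sd, 8),
                 right = draw(params$length_mean, params$length_sd, 8)),
      width = c(left = draw(params$width_mean, params$width_sd, 4),
                right = draw(params$width_mean, params$width_sd, 4)),
      height_ratio = c(left = draw(params$height_ratio_mean, params$height_ratio_sd, 0.1),
                       right = draw(params$height_ratio_mean, params$height_ratio_sd, 0.1)),
      medial_sep = draw(params$medial_sep_mean, params$medial_sep_sd, 6),
      lateral_span = draw(params$lateral_span_mean, params$lateral_span_sd, 30)
    )
  })
}

# Build the bilateral dome mesh of one geometry. Returns vertices, faces,
# side labels and per-facet boundary index lists.
.bilateral_mesh <- function(geom, params) {
  tpl <- .facet_template(params$rings, params$sectors)
  cx <- (geom$medial_sep + geom$lateral_span) / 4
  build_side <- function(side, sign) {
    w <- geom$width[[side]]; l <- geom$length[[side]]
    h <- geom$height_ratio[[side]] * w
    r2 <- pmin(tpl$u^2 + tpl$v^2, 1)
    cbind(x = sign * cx + (w / 2) * tpl$u,
          y = (l / 2) * tpl$v,
          z = h * sqrt(1 - r2))
  }
  vl <- build_side("left", -1)
  vr <- build_side("right", 1)
  nv <- nrow(vl)
  list(vertices = rbind(vl, vr),
       faces = rbind(tpl$faces, tpl$faces + nv),
       side_labels = rep(c("left", "right"), each = nv),
       boundary = list(left = tpl$boundary, right = tpl$boundary + nv))
}

# Area-weighted per-vertex normals.
.vertex_normals <- function(vertices, faces) {
  n <- matrix(0, nrow(vertices), 3)
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fn[, d], faces[, k], sum)
      n[as.integer(names(acc)), d] <- n[as.integer(names(acc)), d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Smooth random field over (x, y), standardised to unit RMS over the mesh.
.smooth_field <- function(vertices, n_waves = 4, wavelength = 15) {
  g <- numeric(nrow(vertices))
  for (k in seq_len(n_waves)) {
    amp <- stats::rnorm(1)
    dir <- stats::runif(1, 0, 2 * pi)
    freq <- stats::runif(1, 0.5, 1.5) * 2 * pi / wavelength
    phase <- stats::runif(1, 0, 2 * pi)
    g <- g + amp * sin(freq * (cos(dir) * vertices[, 1] +
                                 sin(dir) * vertices[, 2]) + phase)
  }
  rms <- sqrt(mean(g^2))
  if (rms == 0) g else g / rms
}

# Landmarks of one facet: extremal boundary points (anterior = +y,
# posterior = -y, lateral = away from the midline, medial = toward it).
.facet_landmarks <- function(vertices, boundary, side) {
  b <- vertices[boundary, , drop = FALSE]
  outward <- if (side == "right") b[, 1] else -b[, 1]
  m <- rbind(anterior = b[which.max(b[, 2]), ],
             posterior = b[which.min(b[, 2]), ],
             lateral = b[which.max(outward), ],
             medial = b[which.min(outward), ])
  m
}

#' Simulate a matched or mismatched articular-surface pair
#'
#' Generates the occipital-condyle ROI of one synthetic individual (a pair of
#' convex ellipsoidal dome patches at their sampled medial/lateral
#' separations) and an atlas-facet ROI that is the congruent counterpart of
#' either the *same* individual (`matched = TRUE`) or an independent one
#' (`matched = FALSE`, drawn from `partner_seed`). The atlas surface receives
#' a smooth random congruency deformation of RMS amplitude `sigma_c` along
#' its vertex normals and is posed by a random rigid displacement, so the
#' registration task is non-trivial. Landmarks are the four extremal boundary
#' points of each facet. Identical `(params, individual_seed, matched,
#' partner_seed)` give bitwise-identical output.
#'
#' @param individual_seed Integer seed identifying the cranium's individual.
#' @param matched Logical: does the atlas belong to the same individual?
#' @param params See [surface_params()].
#' @param partner_seed Seed of the atlas's individual when `matched = FALSE`
#'   (default `individual_seed + 1`).
#' @return Object of class `surface_pair`: list with `oc`, `c1`
#'   ([roi_mesh()] objects), `oc_landmarks`, `c1_landmarks`
#'   ([landmark_set()]), `matched`, `oc_id`, `c1_id`.
#' @export
simulate_surface_pair <- function(individual_seed, matched = TRUE,
                                  params = surface_params(),
                                  partner_seed = individual_seed + 1L) {
  .assert(params$rings >= 2 && params$sectors >= 3,
          "resolution too low: need at least a 3 x 3 vertex patch per facet")
  oc_geom <- .individual_geometry(individual_seed, params)
  oc_parts <- .bilateral_mesh(oc_geom, params)
  oc <- roi_mesh(oc_parts$vertices, oc_parts$faces, oc_parts$side_labels,
                 provenance = "occipital_condyles")
  oc_lm <- landmark_set(
    .facet_landmarks(oc_parts$vertices, oc_parts$boundary$left, "left"),
    .facet_landmarks(oc_parts$vertices, oc_parts$boundary$right, "right"))

  c1_owner <- if (matched) individual_seed else partner_seed
  c1_geom <- .individual_geometry(c1_owner, params)
  c1_parts <- .bilateral_mesh(c1_geom, params)
  verts <- c1_parts$vertices
  if (params$sigma_c > 0) {
    nrm <- .vertex_normals(verts, c1_parts$faces)
    field <- with_seed(c1_owner + 7919L, .smooth_field(verts))
    verts <- verts + params$sigma_c * field * nrm
  }
  c1_lm_raw <- list(
    left = .facet_landmarks(verts, c1_parts$boundary$left, "left"),
    right = .facet_landmarks(verts, c1_parts$boundary$right, "right"))
  pose <- with_seed(individual_seed + 104729L, {
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- stats::runif(1, 5, 25) * pi / 180
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    rigid_transform(R, stats::runif(3, -15, 15))
  })
  verts <- apply_transform(verts, pose)
  c1 <- roi_mesh(verts, c1_parts$faces, c1_parts$side_labels,
                 provenance = "atlas_facets")
  c1_lm <- landmark_set(apply_transform(c1_lm_raw$left, pose),
                        apply_transform(c1_lm_raw$right, pose))
  structure(list(oc = oc, c1 = c1, oc_landmarks = oc_lm, c1_landmarks = c1_lm,
                 matched = matched,
                 oc_id = sprintf("sim%07d", individual_seed),
                 c1_id = sprintf("sim%07d", c1_owner)),
            class = "surface_pair")
}

#' @export
print.surface_pair <- function(x, ...) {
  cat(sprintf("surface_pair: %s OC vs %s C1 (%s)\n", x$oc_id, x$c1_id,
              if (x$matched) "matched" else "mismatched"))
  cat(sprintf("  OC: %d vertices / %d faces; C1: %d vertices / %d faces\n",
              nrow(x$oc$vertices), nrow(x$oc$faces),
              nrow(x$c1$vertices), nrow(x$c1$faces)))
  invisible(x)
}
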