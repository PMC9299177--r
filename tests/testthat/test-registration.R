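# Rigid transforms, landmark alignment, point-to-surface distances, ICP and
# the colour-map export.

test_that("rigid_transform enforces proper orthogonality", {
  expect_error(rigid_transform(diag(3) * 1.01, c(0, 0, 0)), "orthogonal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl, c(0, 0, 0)), "proper")
  tf <- rigid_transform()
  expect_equal(apply_transform(matrix(1:6, 2, 3), tf), matrix(1:6, 2, 3))
})

test_that("transform composition and inversion are consistent", {
  craniosort:::with_seed(21, {
    a <- rand_rigid(); b <- rand_rigid()
    pts <- matrix(rnorm(30), 10, 3)
    expect_equal(apply_transform(pts, compose_transforms(a, b)),
                 apply_transform(apply_transform(pts, b), a))
    ident <- compose_transforms(a, invert_transform(a))
    expect_equal(ident$rotation, diag(3), tolerance = 1e-12)
    expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-12)
  })
})

test_that("landmark alignment recovers identity and pure translation exactly", {
  craniosort:::with_seed(22, {
    P <- matrix(rnorm(24, sd = 10), 8, 3)
    tf0 <- landmark_align(P, P)
    expect_equal(tf0$rotation, diag(3), tolerance = 1e-9)
    expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-9)
    tf1 <- landmark_align(P, sweep(P, 2, c(1, 2, 3), "+"))
    expect_equal(tf1$rotation, diag(3), tolerance = 1e-9)
    expect_equal(tf1$translation, c(1, 2, 3), tolerance = 1e-9)
  })
})

test_that("landmark alignment matches the brute-force optimiser oracle", {
  craniosort:::with_seed(23, {
    for (i in 1:50) {
      P <- matrix(rnorm(24, sd = 10), 8, 3)
      noise <- matrix(rnorm(24, sd = 0.2), 8, 3)
      tf0 <- rand_rigid(max_trans = 20)
      Q <- apply_transform(P, tf0) + noise
      fit <- landmark_align(P, Q)
      # exact-recovery part (noise-free): transform matches the generator
      fit_exact <- landmark_align(P, apply_transform(P, tf0))
      expect_equal(fit_exact$rotation, tf0$rotation, tolerance = 1e-6)
      expect_equal(fit_exact$translation, tf0$translation, tolerance = 1e-6)
      # noisy part: residual equals the independent numeric minimiser
      expect_equal(attr(fit, "rmse"), oracle_rigid_residual(P, Q),
                   tolerance = 1e-6)
    }
  })
})

test_that("collinear landmarks are rejected", {
  P <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(landmark_align(P, P + 1), "collinear")
})

test_that("distance summary is exact on constructed geometries", {
  g <- grid_mesh(5, 5)
  same <- distance_summary(g, g)
  expect_equal(same$rms, 0)
  expect_equal(same$max, 0)

  lifted <- grid_mesh(5, 5, z = function(x, y) 0 * x + 0.5)
  d <- distance_summary(lifted, g)
  expect_equal(d$per_vertex, rep(0.5, 25))
  expect_equal(d$rms, 0.5)
  expect_equal(d$min, 0.5)
  expect_equal(d$max, 0.5)
  expect_equal(d$sd, 0)
})

test_that("point-to-surface distances match the exhaustive triangle oracle", {
  craniosort:::with_seed(24, {
    for (i in 1:3) {
      dst <- grid_mesh(6, 6, z = function(x, y) 0.3 * sin(x) * cos(y))
      pts <- cbind(runif(40, -1, 6), runif(40, -1, 6), runif(40, -2, 2))
      impl <- craniosort:::.closest_on_surface(pts, dst)$dist
      expect_equal(impl, oracle_mesh_distances(pts, dst), tolerance = 1e-9)
    }
    # also on a curved synthetic facet pair
    sp <- simulate_surface_pair(31, params = surface_params(rings = 4, sectors = 10))
    pts <- sp$oc$vertices[seq(1, nrow(sp$oc$vertices), by = 4), ]
    impl <- craniosort:::.closest_on_surface(pts, sp$c1)$dist
    expect_equal(impl, oracle_mesh_distances(pts, sp$c1), tolerance = 1e-9)
  })
})

test_that("point-to-vertex mode gives nearest-vertex distances", {
  g <- grid_mesh(4, 4)
  pts_mesh <- roi_mesh(g$vertices + matrix(c(0.25, 0, 0), nrow(g$vertices), 3,
                                           byrow = TRUE), g$faces)
  d <- distance_summary(pts_mesh, g, mode = "point_to_vertex")
  expect_equal(d$per_vertex, rep(0.25, 16))
  # surface mode is never farther than vertex mode
  ds <- distance_summary(pts_mesh, g)
  expect_true(all(ds$per_vertex <= d$per_vertex + 1e-12))
})

test_that("ICP converges to zero on an identical pair", {
  sp <- simulate_surface_pair(41, params = surface_params(sigma_c = 0,
                                                          rings = 4, sectors = 10))
  s <- icp_refine(sp$oc, sp$oc)
  expect_lt(s$summary$rms, 1e-9)
  expect_true(s$converged)
})

test_that("ICP recovers a known rigid displacement from landmark init", {
  craniosort:::with_seed(25, {
    for (i in 1:3) {
      sp <- simulate_surface_pair(50 + i,
                                  params = surface_params(sigma_c = 0,
                                                          rings = 4, sectors = 10))
      init <- landmark_align(sp$oc_landmarks, sp$c1_landmarks)
      s <- icp_refine(sp$oc, sp$c1, init, convergence_tolerance = 1e-9)
      expect_lt(s$summary$rms, 1e-6)
      # recovered transform maps OC vertices onto the posed copy
      expect_equal(apply_transform(sp$oc$vertices, s$transform),
                   sp$c1$vertices, tolerance = 1e-4)
    }
  })
})

test_that("the ICP RMS trace is non-increasing for random initialisations", {
  craniosort:::with_seed(26, {
    for (i in 1:4) {
      sp <- simulate_surface_pair(60 + i, matched = (i %% 2 == 0),
                                  params = surface_params(rings = 4, sectors = 10))
      s <- icp_refine(sp$oc, sp$c1, rand_rigid(max_trans = 5),
                      max_iterations = 40)
      expect_true(all(diff(s$rms_trace) <= 1e-9))
    }
  })
})

test_that("the final RMS is invariant to a common rigid motion of both meshes", {
  craniosort:::with_seed(27, {
    sp <- simulate_surface_pair(70, matched = FALSE,
                                params = surface_params(rings = 4, sectors = 10))
    init <- landmark_align(sp$oc_landmarks, sp$c1_landmarks)
    base <- icp_refine(sp$oc, sp$c1, init, convergence_tolerance = 1e-9)
    g <- rand_rigid(max_trans = 30)
    move <- function(m) roi_mesh(apply_transform(m$vertices, g), m$faces,
                                 m$side_labels, m$provenance)
    move_lm <- function(lm) landmark_set(apply_transform(lm$left, g),
                                         apply_transform(lm$right, g))
    init2 <- landmark_align(move_lm(sp$oc_landmarks), move_lm(sp$c1_landmarks))
    moved <- icp_refine(move(sp$oc), move(sp$c1), init2,
                        convergence_tolerance = 1e-9)
    expect_equal(moved$summary$rms, base$summary$rms, tolerance = 1e-6)
  })
})

test_that("ICP recovers the amplitude of surface-normal noise", {
  # dst = smooth dome, src = same mesh displaced along vertex normals by
  # N(0, 0.1 mm); the registered point-to-surface RMS estimates sigma
  rms <- craniosort:::with_seed(28, replicate(20, {
    sp <- simulate_surface_pair(sample.int(10000, 1),
                                params = surface_params(sigma_c = 0,
                                                        rings = 5, sectors = 12))
    dst <- sp$oc
    nrm <- craniosort:::.vertex_normals(dst$vertices, dst$faces)
    src <- roi_mesh(dst$vertices + nrm * rnorm(nrow(dst$vertices), sd = 0.1),
                    dst$faces)
    icp_refine(src, dst, max_iterations = 30)$summary$rms
  }))
  expect_gt(mean(rms), 0.07)
  expect_lt(mean(rms), 0.13)
})

test_that("superimpose labels matches and mismatches from identifiers", {
  sp <- simulate_surface_pair(80, params = surface_params(rings = 4, sectors = 10))
  s <- superimpose(sp$oc, sp$c1, sp$oc_landmarks, sp$c1_landmarks,
                   oc_id = sp$oc_id, c1_id = sp$c1_id)
  expect_equal(s$label, "match")
  s2 <- superimpose(sp$oc, sp$c1, sp$oc_landmarks, sp$c1_landmarks,
                    oc_id = "a", c1_id = "b")
  expect_equal(s2$label, "mismatch")
})

test_that("ROI cropping retains exactly the vertices inside the contour", {
  g <- grid_mesh(8, 4)
  # contour enclosing everything
  big <- rbind(c(-1, -1, 0), c(8, -1, 0), c(8, 4, 0), c(-1, 4, 0), c(-1, -1, 0))
  whole <- crop_roi(g, big)
  expect_equal(nrow(whole$vertices), nrow(g$vertices))
  expect_equal(nrow(whole$faces), nrow(g$faces))

  # left half of the grid: x < 3.5 keeps 4 of 8 columns
  half <- rbind(c(-0.5, -0.5, 0), c(3.5, -0.5, 0), c(3.5, 3.5, 0),
                c(-0.5, 3.5, 0), c(-0.5, -0.5, 0))
  left <- crop_roi(g, half)
  expect_equal(nrow(left$vertices), nrow(g$vertices) / 2)
  expect_true(all(left$vertices[, 1] < 3.5))

  expect_error(crop_roi(g, big[1:4, ]), "closed")
  collinear <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 2, 0), c(0, 0, 0))
  expect_error(crop_roi(g, collinear), "collinear")
  far <- rbind(c(100, 100, 0), c(101, 100, 0), c(101, 101, 0), c(100, 100, 0))
  expect_error(crop_roi(g, far), "no vertices")
})

test_that("cropping agrees with a per-vertex point-in-polygon oracle", {
  craniosort:::with_seed(29, {
    g <- grid_mesh(9, 9, z = function(x, y) 0.1 * x * y)
    # random convex contour (convex hull of random points, on the z-plane)
    pts <- cbind(runif(12, 0.5, 7.5), runif(12, 0.5, 7.5))
    hull <- pts[chull(pts), ]
    contour <- cbind(rbind(hull, hull[1, ]), 0)
    cropped <- crop_roi(g, contour)
    expected <- which(apply(g$vertices[, 1:2], 1, oracle_in_polygon,
                            poly = hull))
    expect_equal(sort(attr(cropped, "kept")), sort(expected))
  })
})

test_that("colour-map export round-trips distances through PLY", {
  sp <- simulate_surface_pair(90, params = surface_params(rings = 4, sectors = 10))
  s <- superimpose(sp$oc, sp$c1, sp$oc_landmarks, sp$c1_landmarks)
  path <- tempfile(fileext = ".ply")
  export_colormap(s, sp$oc, path, scale = c(0, 1))
  back <- read_ply(path)
  expect_equal(attr(back, "quality"),
               pmin(pmax(s$summary$per_vertex, 0), 1), tolerance = 1e-7)
  expect_equal(back$vertices, apply_transform(sp$oc$vertices, s$transform),
               tolerance = 1e-7)
  expect_error(export_colormap(s, sp$oc, path, scale = c(1, 1)), "below")
})
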