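# Independent oracles and mesh fixtures, built in code at test time.

# Rectangular grid mesh over [0, (nx-1)*dx] x [0, (ny-1)*dx] with height
# function z(x, y).
grid_mesh <- function(nx, ny, z = function(x, y) 0 * x, dx = 1,
                      provenance = "unknown") {
  g <- expand.grid(x = (seq_len(nx) - 1) * dx, y = (seq_len(ny) - 1) * dx)
  v <- cbind(g$x, g$y, z(g$x, g$y))
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- do.call(rbind, lapply(seq_len(ny - 1), function(j)
    do.call(rbind, lapply(seq_len(nx - 1), function(i)
      rbind(c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
            c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))))))
  roi_mesh(v, faces, provenance = provenance)
}

# Uniformly random proper rotation (QR of a Gaussian matrix, sign-fixed).
rand_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rand_rigid <- function(max_trans = 10) {
  rigid_transform(rand_rotation(), runif(3, -max_trans, max_trans))
}

# Oracle 1: scalar point-to-triangle distance. The closest point is either
# the orthogonal projection (when its barycentric coordinates, computed from
# sub-triangle cross products, are all non-negative) or the closest point on
# one of the three edges.
oracle_point_triangle <- function(p, a, b, c) {
  n <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
         (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
         (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  nn <- sum(n^2)
  seg_dist <- function(u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((u + t * d - p)^2))
  }
  d_edges <- min(seg_dist(a, b), seg_dist(b, c), seg_dist(c, a))
  if (nn < .Machine$double.eps) return(d_edges)  # degenerate triangle
  proj <- p - n * sum((p - a) * n) / nn
  cross_dot <- function(u, v) {
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    sum(w * n)
  }
  inside <- cross_dot(b - a, proj - a) >= -1e-12 * nn &&
            cross_dot(c - b, proj - b) >= -1e-12 * nn &&
            cross_dot(a - c, proj - c) >= -1e-12 * nn
  if (inside) min(sqrt(sum((proj - p)^2)), d_edges) else d_edges
}

# Exhaustive nearest-triangle scan for every point.
oracle_mesh_distances <- function(points, mesh) {
  V <- mesh$vertices
  apply(points, 1, function(p) {
    min(apply(mesh$faces, 1, function(f)
      oracle_point_triangle(p, V[f[1], ], V[f[2], ], V[f[3], ])))
  })
}

# Oracle 2: rigid least-squares fit by general-purpose numeric minimisation
# over Euler angles + translation; returns the achieved RMS residual.
oracle_rigid_residual <- function(P, Q) {
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3, 3, byrow = TRUE)
  }
  obj <- function(par) {
    R <- rot(par[1:3])
    moved <- sweep(P %*% t(R), 2, par[4:6], "+")
    sum((moved - Q)^2)
  }
  best <- Inf
  for (start in list(rep(0, 6), c(pi / 3, -pi / 4, pi / 5, 0, 0, 0),
                     c(-2, 1.5, 2.5, colMeans(Q) - colMeans(P)))) {
    fit <- optim(start, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-15))
    best <- min(best, fit$value)
  }
  sqrt(best / nrow(P))
}

# Oracle 3: scalar even-odd ray-crossing point-in-polygon test (2D).
oracle_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# A small, fully valid random measurement table (not the calibrated
# generator: plain independent positive values).
random_measurement_table <- function(n, seed = 1) {
  craniosort:::with_seed(seed, {
    df <- data.frame(individual_id = sprintf("id%02d", seq_len(n)),
                     sex = sample(c("female", "male"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
    for (nm in setdiff(measurement_schema(), c("individual_id", "sex")))
      df[[nm]] <- runif(n, 10, 40)
    as_measurement_table(df)
  })
}

# Linearly separable toy pairwise dataset: positives far from negatives.
separable_pairs <- function(n_per_class = 20, seed = 1) {
  craniosort:::with_seed(seed, {
    pos <- matrix(100 + rnorm(n_per_class * 9, sd = 0.5), ncol = 9)
    neg <- matrix(-100 + rnorm(n_per_class * 9, sd = 0.5), ncol = 9)
    X <- rbind(pos, neg)
    colnames(X) <- paste0("f", 1:9)
    out <- data.frame(oc_id = sprintf("p%03d", seq_len(2 * n_per_class)),
                      c1_id = sprintf("q%03d", seq_len(2 * n_per_class)),
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(X))
    out$label <- factor(rep(c("correspondent", "non-correspondent"),
                            each = n_per_class),
                        levels = c("non-correspondent", "correspondent"))
    out
  })
}
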