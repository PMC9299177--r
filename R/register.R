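# Two-stage rigid superimposition of articular ROIs: closed-form landmark
# least-squares alignment, iterative closest point refinement against the
# target surface, and per-vertex point-to-surface distance summaries.

#' Rigid transform
#'
#' A proper rigid transform `x -> R x + t` in millimetres. The rotation is
#' validated to be proper orthogonal (no scaling, no reflection) to 1e-9.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 numeric vector (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  .assert(all(dim(rotation) == c(3, 3)), "rotation must be 3 x 3")
  .assert(length(translation) == 3, "translation must have length 3")
  .assert(all(is.finite(rotation)) && all(is.finite(translation)),
          "transform entries must be finite")
  .assert(max(abs(crossprod(rotation) - diag(3))) <= 1e-9,
          "rotation must be orthogonal")
  .assert(abs(det(rotation) - 1) <= 1e-9,
          "rotation must be proper (determinant +1, no reflection)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param points Numeric n x 3 matrix.
#' @param transform A [rigid_transform()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(points, transform) {
  .assert(inherits(transform, "rigid_transform"), "expected a rigid_transform")
  points <- as.matrix(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

# Closed-form least-squares rigid fit (Kabsch/Umeyama, no scaling) mapping
# point set P onto Q (row-wise correspondence).
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cq - as.numeric(R %*% cp))
}

#' Landmark-based rigid alignment
#'
#' Closed-form least-squares rigid fit (no scaling, no reflection) mapping the
#' source landmarks onto the label-matched destination landmarks; the
#' initial-orientation stage of the superimposition protocol.
#'
#' @param src,dst [landmark_set()] objects (or plain n x 3 matrices with
#'   row-wise correspondence, n >= 3).
#' @return A [rigid_transform()] with attribute `"rmse"`, the root mean
#'   square landmark residual (mm) after alignment.
#' @export
landmark_align <- function(src, dst) {
  P <- if (inherits(src, "landmark_set")) .landmark_matrix(src) else as.matrix(src)
  Q <- if (inherits(dst, "landmark_set")) .landmark_matrix(dst) else as.matrix(dst)
  .assert(nrow(P) == nrow(Q) && ncol(P) == 3 && ncol(Q) == 3,
          "landmark sets must be matched n x 3 point sets")
  .assert(nrow(P) >= 3, "at least 3 landmarks are required")
  sv <- svd(sweep(P, 2, colMeans(P)))
  .assert(sv$d[2] > max(sv$d[1], 1) * 1e-9,
          "landmarks are collinear: rigid transform underdetermined")
  tf <- .kabsch(P, Q)
  res <- apply_transform(P, tf) - Q
  attr(tf, "rmse") <- sqrt(mean(rowSums(res^2)))
  tf
}

# Closest point on the triangulated surface of `mesh` for each row of
# `points`. Per point, squared distances to every triangle are computed in
# one vectorised pass (in-triangle orthogonal projection where the projected
# barycentric coordinates admit it, otherwise the nearest of the three
# edges); the closest point itself is reconstructed only for the winning
# triangle.
.closest_on_surface <- function(points, mesh) {
  V <- mesh$vertices
  A <- V[mesh$faces[, 1], , drop = FALSE]
  B <- V[mesh$faces[, 2], , drop = FALSE]
  C <- V[mesh$faces[, 3], , drop = FALSE]
  E0 <- B - A; E1 <- C - A; E2 <- C - B
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); c <- rowSums(E1 * E1)
  det <- pmax(a * c - b * b, .Machine$double.eps)
  ee <- pmax(rowSums(E2 * E2), .Machine$double.eps)
  a_safe <- pmax(a, .Machine$double.eps)
  c_safe <- pmax(c, .Machine$double.eps)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  n <- nrow(points)
  closest <- matrix(NA_real_, n, 3)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    Dx <- points[i, 1] - A[, 1]
    Dy <- points[i, 2] - A[, 2]
    Dz <- points[i, 3] - A[, 3]
    d0 <- E0[, 1] * Dx + E0[, 2] * Dy + E0[, 3] * Dz
    d1 <- E1[, 1] * Dx + E1[, 2] * Dy + E1[, 3] * Dz
    s <- (c * d0 - b * d1) / det
    t <- (a * d1 - b * d0) / det
    inside <- s >= 0 & t >= 0 & s + t <= 1
    # squared distance to the projection A + s E0 + t E1
    rx <- Dx - s * E0[, 1] - t * E1[, 1]
    ry <- Dy - s * E0[, 2] - t * E1[, 2]
    rz <- Dz - s * E0[, 3] - t * E1[, 3]
    d_proj <- rx * rx + ry * ry + rz * rz
    # edge AB
    t1 <- clamp01(d0 / a_safe)
    rx <- Dx - t1 * E0[, 1]; ry <- Dy - t1 * E0[, 2]; rz <- Dz - t1 * E0[, 3]
    d_ab <- rx * rx + ry * ry + rz * rz
    # edge AC
    t2 <- clamp01(d1 / c_safe)
    rx <- Dx - t2 * E1[, 1]; ry <- Dy - t2 * E1[, 2]; rz <- Dz - t2 * E1[, 3]
    d_ac <- rx * rx + ry * ry + rz * rz
    # edge BC
    Gx <- points[i, 1] - B[, 1]
    Gy <- points[i, 2] - B[, 2]
    Gz <- points[i, 3] - B[, 3]
    t3 <- clamp01((E2[, 1] * Gx + E2[, 2] * Gy + E2[, 3] * Gz) / ee)
    rx <- Gx - t3 * E2[, 1]; ry <- Gy - t3 * E2[, 2]; rz <- Gz - t3 * E2[, 3]
    d_bc <- rx * rx + ry * ry + rz * rz
    d_edge <- pmin(d_ab, d_ac, d_bc)
    d_tri <- ifelse(inside, pmin(d_proj, d_edge), d_edge)
    j <- which.min(d_tri)
    closest[i, ] <- if (inside[j] && d_proj[j] <= d_edge[j]) {
      A[j, ] + s[j] * E0[j, ] + t[j] * E1[j, ]
    } else if (d_ab[j] <= d_ac[j] && d_ab[j] <= d_bc[j]) {
      A[j, ] + t1[j] * E0[j, ]
    } else if (d_ac[j] <= d_bc[j]) {
      A[j, ] + t2[j] * E1[j, ]
    } else {
      B[j, ] + t3[j] * E2[j, ]
    }
    dist[i] <- sqrt(d_tri[j])
  }
  list(closest = closest, dist = dist)
}

.closest_vertex <- function(points, mesh) {
  V <- mesh$vertices
  n <- nrow(points)
  closest <- matrix(NA_real_, n, 3)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(V, 2, points[i, ])^2)
    j <- which.min(d2)
    closest[i, ] <- V[j, ]
    dist[i] <- sqrt(d2[j])
  }
  list(closest = closest, dist = dist)
}

#' Per-vertex distance summary of a superimposed mesh pair
#'
#' Unsigned distance from each (transformed) source vertex to the nearest
#' point on the destination surface, summarised as RMS, minimum, maximum and
#' SD -- the outputs reported per superimposition. `point_to_vertex` mode
#' (nearest destination vertex instead of nearest surface point) is provided
#' for sensitivity analysis; the surface mode is robust to the differing
#' resolutions of meshes from different scanners.
#'
#' @param src,dst [roi_mesh()] objects (source is the moving mesh).
#' @param transform [rigid_transform()] applied to `src` before measuring.
#' @param mode `"point_to_surface"` (default) or `"point_to_vertex"`.
#' @return Object of class `distance_summary`: list with `rms`, `min`, `max`,
#'   `sd` (all mm) and the `per_vertex` distance vector.
#' @export
distance_summary <- function(src, dst, transform = rigid_transform(),
                             mode = c("point_to_surface", "point_to_vertex")) {
  mode <- match.arg(mode)
  .assert(inherits(src, "roi_mesh") && inherits(dst, "roi_mesh"),
          "src and dst must be roi_mesh objects")
  pts <- apply_transform(src$vertices, transform)
  d <- if (mode == "point_to_surface") .closest_on_surface(pts, dst)$dist
       else .closest_vertex(pts, dst)$dist
  structure(list(rms = sqrt(mean(d^2)), min = min(d), max = max(d),
                 sd = stats::sd(d), per_vertex = d, mode = mode),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("distance_summary (%s, n = %d): RMS %.4f  min %.4f  max %.4f  SD %.4f mm\n",
              x$mode, length(x$per_vertex), x$rms, x$min, x$max, x$sd))
  invisible(x)
}

#' Iterative closest point refinement
#'
#' Alternates nearest-point correspondence (from transformed source vertices
#' to the destination surface) with a closed-form rigid update until the
#' correspondence RMS changes by less than `convergence_tolerance` or
#' `max_iterations` is reached. The per-iteration RMS trace is non-increasing
#' by construction. No correspondence rejection is applied.
#'
#' @param src,dst [roi_mesh()] objects; `src` moves onto `dst`.
#' @param init Initial [rigid_transform()], typically from [landmark_align()].
#' @param max_iterations Iteration cap (default 100).
#' @param convergence_tolerance Minimum RMS improvement (mm) to continue.
#' @param mode Distance mode, as in [distance_summary()].
#' @param oc_id,c1_id Optional specimen identifiers carried into the result.
#' @return Object of class `superimposition`: list with `oc_id`, `c1_id`,
#'   `transform`, `summary` (a [distance_summary()]), `label` (`"match"` iff
#'   the two ids are equal, else `"mismatch"`, `NA` if ids are absent),
#'   `converged`, `iterations` and `rms_trace`.
#' @export
icp_refine <- function(src, dst, init = rigid_transform(),
                       max_iterations = 100, convergence_tolerance = 1e-6,
                       mode = c("point_to_surface", "point_to_vertex"),
                       oc_id = NULL, c1_id = NULL) {
  mode <- match.arg(mode)
  .assert(inherits(src, "roi_mesh") && inherits(dst, "roi_mesh"),
          "src and dst must be roi_mesh objects")
  .assert(inherits(init, "rigid_transform"), "init must be a rigid_transform")
  .assert(max_iterations >= 1, "max_iterations must be at least 1")
  closest_fun <- if (mode == "point_to_surface") .closest_on_surface else .closest_vertex
  tf <- init
  P0 <- src$vertices
  trace <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  iterations <- 0
  for (it in seq_len(max_iterations)) {
    pts <- apply_transform(P0, tf)
    corr <- closest_fun(pts, dst)
    # rigid update mapping original source points onto current correspondences
    tf <- .kabsch(P0, corr$closest)
    pts <- apply_transform(P0, tf)
    # correspondence RMS after the update: non-increasing across iterations
    # (re-matching can only shorten each correspondence, the rigid update can
    # only shorten the sum of squares)
    rms <- sqrt(mean(rowSums((pts - corr$closest)^2)))
    trace <- c(trace, rms)
    iterations <- it
    if (prev_rms - rms < convergence_tolerance) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
  }
  summ <- distance_summary(src, dst, tf, mode = mode)
  label <- if (is.null(oc_id) || is.null(c1_id)) NA_character_
           else if (identical(oc_id, c1_id)) "match" else "mismatch"
  structure(list(oc_id = oc_id, c1_id = c1_id, transform = tf, summary = summ,
                 label = label, converged = converged, iterations = iterations,
                 rms_trace = trace),
            class = "superimposition")
}

#' @export
print.superimposition <- function(x, ...) {
  id <- if (is.null(x$oc_id)) "" else sprintf(" %s vs %s (%s)", x$oc_id, x$c1_id, x$label)
  cat(sprintf("superimposition%s: RMS %.4f mm after %d ICP iteration(s)%s\n",
              id, x$summary$rms, x$iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Full two-stage superimposition of an OC-C1 ROI pair
#'
#' Landmark least-squares initialisation followed by ICP refinement. By
#' convention the occipital-condyle mesh is the moving surface registered
#' onto the atlas mesh; `swap = TRUE` reverses the roles.
#'
#' @param oc,c1 [roi_mesh()] objects.
#' @param oc_landmarks,c1_landmarks [landmark_set()] objects.
#' @param swap Register C1 onto OC instead.
#' @param oc_id,c1_id Optional identifiers.
#' @param ... Passed to [icp_refine()].
#' @return A `superimposition` (see [icp_refine()]).
#' @export
superimpose <- function(oc, c1, oc_landmarks, c1_landmarks, swap = FALSE,
                        oc_id = NULL, c1_id = NULL, ...) {
  if (swap) {
    init <- landmark_align(c1_landmarks, oc_landmarks)
    icp_refine(c1, oc, init, oc_id = oc_id, c1_id = c1_id, ...)
  } else {
    init <- landmark_align(oc_landmarks, c1_landmarks)
    icp_refine(oc, c1, init, oc_id = oc_id, c1_id = c1_id, ...)
  }
}

#' Export a superimposition colour map
#'
#' Writes the transformed moving mesh as PLY with the per-vertex distances as
#' the `quality` property and a blue-green-red colour ramp over `scale`
#' (values clipped), the usual visual first-pass readout of a superimposition.
#'
#' @param s A `superimposition` from [icp_refine()] or [superimpose()]. The
#'   moving mesh is re-supplied as `src` (the superimposition stores only the
#'   summary, not the mesh).
#' @param src The moving [roi_mesh()].
#' @param path Output `.ply` path.
#' @param scale Length-2 numeric, colour scale bounds in mm (min < max).
#' @return `path`, invisibly.
#' @export
export_colormap <- function(s, src, path, scale = NULL) {
  .assert(inherits(s, "superimposition"), "expected a superimposition")
  .assert(inherits(src, "roi_mesh"), "src must be the moving roi_mesh")
  d <- s$summary$per_vertex
  .assert(length(d) == nrow(src$vertices),
          "src does not match the superimposed mesh (vertex count differs)")
  if (is.null(scale)) scale <- c(0, max(d, 1e-12))
  .assert(is.numeric(scale) && length(scale) == 2, "scale must be length-2 numeric")
  .assert(scale[1] < scale[2], "scale minimum must be below scale maximum")
  moved <- roi_mesh(apply_transform(src$vertices, s$transform), src$faces,
                    side_labels = src$side_labels, provenance = src$provenance)
  write_ply(moved, path, quality = d, scale = scale)
}
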