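# Triangle-mesh data model for articular-surface ROIs, mesh file I/O
# (STL ASCII/binary, PLY ASCII) and contour-based ROI cropping.

#' Articular-surface ROI mesh
#'
#' A triangulated open surface patch in millimetres: the bilateral occipital
#' condyle pair or the bilateral atlas superior-facet pair, kept in original
#' spatial relation (the inter-facet spacing is part of the signal).
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @param side_labels Optional character/factor vector (`left`/`right`) of
#'   per-vertex facet membership.
#' @param provenance `"occipital_condyles"`, `"atlas_facets"` or `"unknown"`.
#' @return Object of class `roi_mesh`.
#' @export
roi_mesh <- function(vertices, faces, side_labels = NULL,
                     provenance = c("unknown", "occipital_condyles", "atlas_facets")) {
  provenance <- match.arg(provenance)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  .assert(ncol(vertices) == 3, "vertices must be an n x 3 matrix")
  .assert(nrow(vertices) >= 3, "a mesh needs at least 3 vertices")
  .assert(all(is.finite(vertices)), "vertex coordinates must be finite")
  .assert(ncol(faces) == 3, "faces must be an m x 3 matrix")
  .assert(all(faces >= 1) && all(faces <= nrow(vertices)),
          "face indices must reference existing vertices")
  if (!is.null(side_labels)) {
    side_labels <- as.character(side_labels)
    .assert(length(side_labels) == nrow(vertices),
            "side_labels must have one entry per vertex")
    .assert(all(side_labels %in% c("left", "right")),
            "side_labels must be 'left' or 'right'")
  }
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, faces = faces,
                 side_labels = side_labels, provenance = provenance),
            class = "roi_mesh")
}

#' @export
print.roi_mesh <- function(x, ...) {
  cat(sprintf("roi_mesh (%s): %d vertices, %d faces\n",
              x$provenance, nrow(x$vertices), nrow(x$faces)))
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  extent (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

.LANDMARK_LABELS <- c("anterior", "posterior", "lateral", "medial")

#' Facet landmark set
#'
#' Four labelled edge points (anterior, posterior, lateral, medial) per facet
#' (left and right), in millimetres: the input of the landmark-based
#' registration stage.
#'
#' @param left,right Numeric 4 x 3 matrices with row names
#'   `anterior`, `posterior`, `lateral`, `medial`.
#' @return Object of class `landmark_set` (a list with elements `left`,
#'   `right`).
#' @export
landmark_set <- function(left, right) {
  fix <- function(m, side) {
    m <- as.matrix(m)
    .assert(ncol(m) == 3 && nrow(m) == 4,
            sprintf("%s facet landmarks must be a 4 x 3 matrix", side))
    .assert(!is.null(rownames(m)) && setequal(rownames(m), .LANDMARK_LABELS),
            sprintf("%s facet landmarks must be labelled %s", side,
                    paste(.LANDMARK_LABELS, collapse = "/")))
    .assert(all(is.finite(m)), "landmark coordinates must be finite")
    m <- m[.LANDMARK_LABELS, , drop = FALSE]
    colnames(m) <- NULL
    m
  }
  structure(list(left = fix(left, "left"), right = fix(right, "right")),
            class = "landmark_set")
}

# 8 x 3 matrix of landmarks in fixed (side, label) order.
.landmark_matrix <- function(lm) {
  .assert(inherits(lm, "landmark_set"), "expected a landmark_set")
  rbind(lm$left, lm$right)
}

# --- STL --------------------------------------------------------------------

# Merge byte-identical vertices of a triangle soup into an indexed mesh.
.weld_vertices <- function(tri) {
  key <- apply(tri, 1, function(v) paste(sprintf("%.9e", v), collapse = "|"))
  first <- !duplicated(key)
  verts <- tri[first, , drop = FALSE]
  idx <- match(key, key[first])
  list(vertices = verts, faces = matrix(idx, ncol = 3, byrow = TRUE))
}

#' Read an STL surface mesh
#'
#' Reads ASCII or binary STL (auto-detected from the declared triangle count)
#' and welds coincident triangle corners into shared vertices. Units are
#' taken as millimetres; STL carries no unit metadata.
#'
#' @param path Path to the `.stl` file.
#' @param provenance Passed to [roi_mesh()].
#' @return A [roi_mesh()].
#' @export
read_stl <- function(path, provenance = "unknown") {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  size <- file.info(path)$size
  is_binary <- FALSE
  if (size >= 84) {
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (!is.na(ntri) && ntri > 0 && size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    tri <- matrix(NA_real_, 3 * ntri, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      invisible(readBin(con, "raw", 2))
      tri[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    .assert(length(vl) > 0 && length(vl) %% 3 == 0,
            sprintf("malformed ASCII STL: %s", path))
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  }
  w <- .weld_vertices(tri)
  roi_mesh(w$vertices, w$faces, provenance = provenance)
}

#' Write an STL surface mesh
#'
#' @param mesh A [roi_mesh()].
#' @param path Output path.
#' @param binary Write binary STL (`TRUE`, default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  .assert(inherits(mesh, "roi_mesh"), "expected a roi_mesh")
  V <- mesh$vertices; F <- mesh$faces
  normal <- function(a, b, c) {
    n <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
           (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
           (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    len <- sqrt(sum(n^2))
    if (len > 0) n / len else c(0, 0, 1)
  }
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(F))) {
      a <- V[F[i, 1], ]; b <- V[F[i, 2], ]; cc <- V[F[i, 3], ]
      writeBin(as.numeric(c(normal(a, b, cc), a, b, cc)), con,
               size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid craniosort", con)
    for (i in seq_len(nrow(F))) {
      a <- V[F[i, 1], ]; b <- V[F[i, 2], ]; cc <- V[F[i, 3], ]
      n <- normal(a, b, cc)
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", n[1], n[2], n[3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", a[1], a[2], a[3]),
        sprintf("      vertex %.9e %.9e %.9e", b[1], b[2], b[3]),
        sprintf("      vertex %.9e %.9e %.9e", cc[1], cc[2], cc[3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid craniosort", con)
  }
  invisible(path)
}

# --- PLY --------------------------------------------------------------------

#' Write an ASCII PLY mesh, optionally with a per-vertex scalar field
#'
#' The scalar field is stored as the standard `quality` vertex property,
#' alongside an RGB colour rendering of it (blue = low, green = mid,
#' red = high over `scale`), so any PLY viewer shows the distance colour map.
#'
#' @param mesh A [roi_mesh()].
#' @param path Output path.
#' @param quality Optional numeric per-vertex scalar (e.g. distances, mm).
#' @param scale Length-2 numeric: scalar values are clipped to this range for
#'   colouring. Defaults to the quality range.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, quality = NULL, scale = NULL) {
  .assert(inherits(mesh, "roi_mesh"), "expected a roi_mesh")
  V <- mesh$vertices; F <- mesh$faces
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(V)),
              "property float x", "property float y", "property float z")
  body_v <- apply(V, 1, function(v) sprintf("%.9e %.9e %.9e", v[1], v[2], v[3]))
  if (!is.null(quality)) {
    .assert(length(quality) == nrow(V), "quality must have one value per vertex")
    if (is.null(scale)) scale <- range(quality)
    .assert(scale[1] < scale[2], "scale minimum must be below scale maximum")
    q <- pmin(pmax(quality, scale[1]), scale[2])
    t <- (q - scale[1]) / (scale[2] - scale[1])
    col <- grDevices::colorRamp(c("blue", "green", "red"))(t)
    header <- c(header, "property uchar red", "property uchar green",
                "property uchar blue", "property float quality")
    body_v <- sprintf("%s %d %d %d %.9e", body_v,
                      round(col[, 1]), round(col[, 2]), round(col[, 3]), q)
  }
  header <- c(header, sprintf("element face %d", nrow(F)),
              "property list uchar int vertex_indices", "end_header")
  body_f <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
  writeLines(c(header, body_v, body_f), path)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' Supports the subset written by [write_ply()]: float vertex properties
#' (`x`, `y`, `z`, optional colour and `quality`) and triangular faces.
#'
#' @param path Path to the `.ply` file.
#' @param provenance Passed to [roi_mesh()].
#' @return A [roi_mesh()]; if a `quality` property is present it is attached
#'   as attribute `"quality"`.
#' @export
read_ply <- function(path, provenance = "unknown") {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  .assert(identical(trimws(lines[1]), "ply"), "not a PLY file")
  end <- match("end_header", trimws(lines))
  .assert(!is.na(end), "PLY header not terminated")
  header <- trimws(lines[seq_len(end)])
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  vstart <- match("element vertex", substr(header, 1, 14))
  fstart <- match("element face", substr(header, 1, 12))
  vprops <- header[seq(vstart + 1, fstart - 1)]
  vprops <- sub("^property\\s+\\S+\\s+", "", vprops[grepl("^property", vprops)])
  vlines <- strsplit(trimws(lines[end + seq_len(nv)]), "\\s+")
  vmat <- do.call(rbind, lapply(vlines, as.numeric))
  colnames(vmat) <- vprops
  flines <- strsplit(trimws(lines[end + nv + seq_len(nf)]), "\\s+")
  fmat <- do.call(rbind, lapply(flines, function(p) as.integer(p[2:4]) + 1L))
  mesh <- roi_mesh(vmat[, c("x", "y", "z")], fmat, provenance = provenance)
  if ("quality" %in% colnames(vmat)) attr(mesh, "quality") <- vmat[, "quality"]
  mesh
}

# --- landmark JSON ----------------------------------------------------------

#' Read / write facet landmarks as JSON
#'
#' JSON layout: `{"left": {"anterior": [x,y,z], ...}, "right": {...}}` with
#' explicit label keys (no positional ordering), coordinates in mm.
#'
#' @param path File path.
#' @return [landmark_set()] for the reader; `path` invisibly for the writer.
#' @export
read_landmarks <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  .assert(all(c("left", "right") %in% names(j)),
          "landmark JSON must contain 'left' and 'right' facets")
  to_mat <- function(side) {
    .assert(setequal(names(side), .LANDMARK_LABELS),
            "each facet needs anterior/posterior/lateral/medial points")
    do.call(rbind, side[.LANDMARK_LABELS])
  }
  landmark_set(to_mat(j$left), to_mat(j$right))
}

#' @rdname read_landmarks
#' @param landmarks A [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  .assert(inherits(landmarks, "landmark_set"), "expected a landmark_set")
  as_list <- function(m) stats::setNames(
    lapply(seq_len(nrow(m)), function(i) unname(m[i, ])), rownames(m))
  jsonlite::write_json(list(left = as_list(landmarks$left),
                            right = as_list(landmarks$right)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

# --- ROI cropping -----------------------------------------------------------

#' Crop a mesh to the region enclosed by a surface contour
#'
#' Emulates the manual articular-contour selection step: the ordered 3D
#' contour polyline (placed on the surface) is projected, together with all
#' mesh vertices, onto the contour's best-fit plane, and vertices inside the
#' 2D polygon are retained. Faces survive only if all three corners are kept.
#'
#' @param mesh A [roi_mesh()].
#' @param contour Numeric p x 3 matrix of ordered contour points; the contour
#'   must be closed (first and last point coincide within `tol`).
#' @param tol Closure tolerance in mm.
#' @return The cropped [roi_mesh()], with attribute `"kept"` holding the
#'   original indices of retained vertices.
#' @export
crop_roi <- function(mesh, contour, tol = 1e-6) {
  .assert(inherits(mesh, "roi_mesh"), "expected a roi_mesh")
  contour <- as.matrix(contour)
  .assert(ncol(contour) == 3 && nrow(contour) >= 4,
          "contour must be a closed polyline of at least 3 distinct 3D points")
  .assert(sqrt(sum((contour[1, ] - contour[nrow(contour), ])^2)) <= tol,
          "contour must be closed (first and last points must coincide)")
  ring <- contour[-nrow(contour), , drop = FALSE]
  ctr <- colMeans(ring)
  sv <- svd(sweep(ring, 2, ctr))
  .assert(sv$d[2] > max(sv$d[1], 1) * 1e-9,
          "degenerate contour: points are collinear")
  basis <- sv$v[, 1:2]
  poly2 <- sweep(ring, 2, ctr) %*% basis
  pts2 <- sweep(mesh$vertices, 2, ctr) %*% basis
  inside <- mgcv::in.out(rbind(poly2, poly2[1, ]), pts2)
  .assert(any(inside), "contour selects no vertices")
  keep <- which(inside)
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  fkeep <- mesh$faces[rowSums(matrix(inside[mesh$faces], ncol = 3)) == 3, ,
                      drop = FALSE]
  .assert(nrow(fkeep) > 0, "contour selects no complete faces")
  out <- roi_mesh(mesh$vertices[keep, , drop = FALSE],
                  matrix(remap[fkeep], ncol = 3),
                  side_labels = mesh$side_labels[keep],
                  provenance = mesh$provenance)
  attr(out, "kept") <- keep
  out
}
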