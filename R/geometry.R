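## Geometry core: coordinate frames, rigid alignment, mesh queries,
## point-cloud downsampling. All coordinates are millimeters, RAS axes.

#' Triangulated surface mesh
#'
#' Container for one head or brain surface: an M x 3 vertex matrix in
#' world millimeters and a T x 3 matrix of 1-based vertex indices.
#'
#' @param vertices numeric M x 3 matrix of vertex positions (mm).
#' @param faces integer T x 3 matrix of 1-based vertex indices.
#' @param allow_degenerate keep zero-area faces instead of erroring.
#' @return an object of class `"trimesh"`.
#' @export
trimesh <- function(vertices, faces, allow_degenerate = FALSE) {
  vertices <- as_point_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L)
    pmri_stop("invalid_mesh", "'faces' must have 3 columns")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      pmri_stop("invalid_mesh", "face indices out of range")
    if (!allow_degenerate) {
      a <- vertices[faces[, 1], , drop = FALSE]
      ab <- vertices[faces[, 2], , drop = FALSE] - a
      ac <- vertices[faces[, 3], , drop = FALSE] - a
      area2 <- row_norms(cross3(ab, ac))
      if (any(area2 < 1e-12))
        pmri_stop("invalid_mesh", "mesh contains zero-area faces")
    }
  }
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  n <- cross3(mesh$vertices[mesh$faces[, 2], , drop = FALSE] - a,
              mesh$vertices[mesh$faces[, 3], , drop = FALSE] - a)
  n / pmax(row_norms(n), 1e-300)
}

#' Anatomical fiducial landmarks
#'
#' Nasion and left/right preauricular points, the three landmarks that
#' anchor the head coordinate frame and the rigid MRI-to-head alignment.
#'
#' @param nasion,lpa,rpa numeric length-3 positions (mm).
#' @param frame frame identifier, e.g. `"head"` or `"mri"`.
#' @return an object of class `"fiducials"`.
#' @export
fiducials <- function(nasion, lpa, rpa, frame = "unknown") {
  m <- rbind(as.numeric(nasion), as.numeric(lpa), as.numeric(rpa))
  m <- as_point_matrix(m, "fiducials")
  # non-collinearity: triangle area must exceed 1e-6 mm^2
  area <- 0.5 * row_norms(cross3(m[2, , drop = FALSE] - m[1, , drop = FALSE],
                                 m[3, , drop = FALSE] - m[1, , drop = FALSE]))
  if (area <= 1e-6)
    pmri_stop("invalid_fiducials", "fiducials are collinear")
  structure(list(nasion = m[1, ], lpa = m[2, ], rpa = m[3, ], frame = frame),
            class = "fiducials")
}

fiducial_matrix <- function(fids) rbind(fids$nasion, fids$lpa, fids$rpa)

#' Rigid (rotation + translation) transform
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 vector (mm).
#' @param from_frame,to_frame frame identifiers.
#' @return an object of class `"rigid_transform"`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            from_frame = "a", to_frame = "b") {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    pmri_stop("invalid_transform", "rotation is not a proper orthonormal matrix")
  structure(list(rotation = rotation, translation = translation,
                 from_frame = from_frame, to_frame = to_frame),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform()].
#' @param points n x 3 matrix (mm).
#' @return transformed n x 3 matrix.
#' @export
apply_rigid <- function(tf, points) {
  p <- as_point_matrix(points)
  sweep(p %*% t(tf$rotation), 2, -tf$translation)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse transform (frames swapped).
#' @export
invert_rigid <- function(tf) {
  rigid_transform(t(tf$rotation), -t(tf$rotation) %*% tf$translation,
                  from_frame = tf$to_frame, to_frame = tf$from_frame)
}

#' Compose two rigid transforms (`b` after `a`)
#' @param b,a rigid transforms; the result maps `x -> b(a(x))`.
#' @return combined rigid transform.
#' @export
compose_rigid <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  b$rotation %*% a$translation + b$translation,
                  from_frame = a$from_frame, to_frame = b$to_frame)
}

rigid_to_mat4 <- function(tf) {
  m <- diag(4)
  m[1:3, 1:3] <- tf$rotation
  m[1:3, 4] <- tf$translation
  m
}

#' Head coordinate frame from fiducials
#'
#' Neuromag-style convention: the origin is the orthogonal projection of
#' the nasion onto the LPA-RPA line, +x points toward RPA, +y toward the
#' nasion, +z = x cross y (up). Returns the transform taking points from
#' the fiducials' frame into this head frame.
#'
#' @param fids a [fiducials()] object.
#' @return a [rigid_transform()] from `fids$frame` to `"head"`.
#' @export
define_head_frame <- function(fids) {
  ex <- fids$rpa - fids$lpa
  ex <- ex / sqrt(sum(ex^2))
  # origin: projection of nasion on the LPA-RPA line
  origin <- fids$lpa + sum((fids$nasion - fids$lpa) * ex) * ex
  ey <- fids$nasion - origin
  ny <- sqrt(sum(ey^2))
  if (ny < 1e-9)
    pmri_stop("invalid_fiducials", "nasion lies on the LPA-RPA line")
  ey <- ey / ny
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  rot <- rbind(ex, ey, ez)
  dimnames(rot) <- NULL
  rigid_transform(rot, -rot %*% origin,
                  from_frame = fids$frame, to_frame = "head")
}

#' Rigid landmark alignment (orthogonal Procrustes, no scaling)
#'
#' Least-squares rigid transform `T` minimizing `sum ||T(src_i) - dst_i||^2`
#' over corresponding landmark pairs (Kabsch algorithm).
#'
#' @param src,dst n x 3 matrices of corresponding points, n >= 3,
#'   non-collinear.
#' @param from_frame,to_frame frame identifiers for the result.
#' @return a [rigid_transform()].
#' @export
fit_rigid_landmarks <- function(src, dst, from_frame = "a", to_frame = "b") {
  src <- as_point_matrix(src, "src"); dst <- as_point_matrix(dst, "dst")
  if (nrow(src) != nrow(dst))
    pmri_stop("insufficient_landmarks", "src and dst must have equal lengths")
  if (nrow(src) < 3L)
    pmri_stop("insufficient_landmarks", "need at least 3 landmark pairs")
  cs <- colMeans(src); cd <- colMeans(dst)
  s0 <- sweep(src, 2, cs); d0 <- sweep(dst, 2, cd)
  if (min(svd(s0)$d[1:2]) < 1e-9)
    pmri_stop("insufficient_landmarks", "landmarks are collinear")
  h <- crossprod(s0, d0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(rot, cd - rot %*% cs, from_frame, to_frame)
}

#' Exact point-to-surface distances
#'
#' Distance from each query point to the nearest point on the triangulated
#' surface, minimized over every face (not just vertices).
#'
#' @param points n x 3 query points (mm).
#' @param mesh a [trimesh()].
#' @param return_closest also return the n x 3 matrix of closest points.
#' @return numeric vector of n non-negative distances (mm), or a list
#'   `(dist, closest)` when `return_closest` is `TRUE`.
#' @export
point_mesh_distances <- function(points, mesh, return_closest = FALSE) {
  points <- as_point_matrix(points)
  if (!inherits(mesh, "trimesh") || nrow(mesh$faces) == 0L)
    pmri_stop("empty_geometry", "mesh is empty")
  if (nrow(points) == 0L) {
    return(if (return_closest)
      list(dist = numeric(0), closest = matrix(0, 0, 3)) else numeric(0))
  }
  res <- cpp_point_mesh_dist(points, mesh$vertices, mesh$faces - 1L)
  if (return_closest) res else res$dist
}

#' Radial projection of points onto a surface
#'
#' Projects each point along the ray from `origin` through the point onto
#' the mesh, taking the outermost (farthest-from-origin) crossing; this is
#' how digitization points, which lie outside the scalp, are paired with
#' template-scalp control points. Rays that miss the surface fall back to
#' the nearest surface point and are flagged.
#'
#' @param points n x 3 points (mm).
#' @param mesh a [trimesh()]; `origin` must be inside it.
#' @param origin length-3 ray origin (default head-frame origin).
#' @return list with `points` (n x 3 on-surface positions) and `fallback`
#'   (logical, `TRUE` where the ray missed and the nearest point was used).
#' @export
radial_project <- function(points, mesh, origin = c(0, 0, 0)) {
  points <- as_point_matrix(points)
  if (!inherits(mesh, "trimesh") || nrow(mesh$faces) == 0L)
    pmri_stop("empty_geometry", "mesh is empty")
  origin <- as.numeric(origin)
  dirs <- sweep(points, 2, origin)
  len <- row_norms(dirs)
  ok <- len > 1e-12
  out <- points
  fallback <- !ok  # points at the origin have no ray direction
  if (any(ok)) {
    d <- dirs[ok, , drop = FALSE] / len[ok]
    hits <- cpp_ray_mesh_farthest(origin, d, mesh$vertices, mesh$faces - 1L)
    hit <- hits$hit == 1L
    proj <- matrix(origin, sum(ok), 3, byrow = TRUE) + d * hits$t
    idx <- which(ok)
    out[idx[hit], ] <- proj[hit, , drop = FALSE]
    fallback[idx[!hit]] <- TRUE
  }
  if (any(fallback)) {
    near <- point_mesh_distances(points[fallback, , drop = FALSE], mesh,
                                 return_closest = TRUE)
    out[fallback, ] <- near$closest
  }
  list(points = out, fallback = fallback)
}

#' Farthest-point downsampling of a point cloud
#'
#' Greedy farthest-first traversal started from the point nearest the
#' cloud centroid, used to cap digitization density before warping. When
#' the cloud already has at most `n_max` points it is returned unchanged.
#'
#' @param points n x 3 matrix (mm).
#' @param n_max maximum number of points to keep (>= 1).
#' @param seed integer; only used to break exact distance ties.
#' @return list with `points` (kept rows) and `index` (row indices kept,
#'   in selection order for the downsampled case).
#' @export
farthest_point_downsample <- function(points, n_max, seed = 0L) {
  points <- as_point_matrix(points)
  n <- nrow(points)
  if (n_max < 1L) pmri_stop("invalid_argument", "n_max must be >= 1")
  if (n <= n_max) return(list(points = points, index = seq_len(n)))
  # tie-break: rank by a seeded shuffle, prefer lower shuffled rank
  perm <- with_seed(seed, sample.int(n))
  # traversal is anchored at the point nearest the centroid, which seeds
  # the distance field but is only kept if it is re-selected as farthest
  ctr <- colMeans(points)
  d0 <- row_norms(sweep(points, 2, ctr))
  first <- which(d0 == min(d0))
  first <- first[which.min(perm[first])]
  sel <- integer(n_max)
  mind <- row_norms(sweep(points, 2, points[first, ]))
  for (k in seq_len(n_max)) {
    best <- which(mind == max(mind))
    nxt <- best[which.min(perm[best])]
    sel[k] <- nxt
    dn <- row_norms(sweep(points, 2, points[nxt, ]))
    mind <- pmin(mind, dn)
  }
  list(points = points[sel, , drop = FALSE], index = sel)
}

#' Signed distances to the fiducial plane
#'
#' Plane through nasion/LPA/RPA with the normal oriented toward `toward`
#' (typically the head-point centroid, i.e. the top of the head).
#'
#' @param fids a [fiducials()] object.
#' @param points n x 3 matrix.
#' @param toward length-3 point fixing the positive side.
#' @return numeric vector of signed distances (mm), positive on the
#'   `toward` side.
#' @export
fiducial_plane_distances <- function(fids, points, toward) {
  m <- fiducial_matrix(fids)
  n <- cross3(m[2, , drop = FALSE] - m[1, , drop = FALSE],
              m[3, , drop = FALSE] - m[1, , drop = FALSE])[1, ]
  n <- n / sqrt(sum(n^2))
  s <- sum((as.numeric(toward) - m[1, ]) * n)
  if (abs(s) < 1e-6)
    pmri_stop("orientation_error", "cannot orient fiducial plane: reference point lies on it")
  if (s < 0) n <- -n
  points <- as_point_matrix(points)
  as.numeric(sweep(points, 2, m[1, ]) %*% n)
}
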