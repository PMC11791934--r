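## Surface-congruence metrics: mean point-to-point distance on
## corresponding meshes, Hausdorff distance, convex-hull envelopes, and
## boxplot-style summary statistics.

#' Mean point-to-point distance between corresponding meshes
#'
#' `D = mean_i ||r_ai - r_bi||` over corresponding vertices; requires the
#' two meshes to share one template topology (identical vertex counts and
#' ordering).
#'
#' @param a,b [trimesh()] objects with identical vertex counts.
#' @return list `(mean, per_vertex)` in mm.
#' @export
mean_pointwise_distance <- function(a, b) {
  if (nrow(a$vertices) != nrow(b$vertices))
    pmri_stop("correspondence_error",
              "vertex counts differ; use hausdorff_distance() instead")
  d <- row_norms(a$vertices - b$vertices)
  list(mean = mean(d), per_vertex = d)
}

#' Hausdorff distance between two surfaces
#'
#' Directed distance = max over the vertices of one mesh of the exact
#' point-to-surface distance to the other (surface, not vertex set, on
#' the target side); symmetrized by the max of the two directions.
#'
#' @param a,b [trimesh()] objects.
#' @param symmetric take the max of both directions (default) or only
#'   a -> b.
#' @return scalar distance (mm).
#' @export
hausdorff_distance <- function(a, b, symmetric = TRUE) {
  dab <- max(point_mesh_distances(a$vertices, b))
  if (!symmetric) return(dab)
  max(dab, max(point_mesh_distances(b$vertices, a)))
}

#' Boxplot-style distance statistics
#'
#' Quartiles use linear interpolation between order statistics; the
#' outlier and extreme fractions are the shares of values beyond the
#' `Q3 + 1.5 IQR` and `Q3 + 3.0 IQR` fences.
#'
#' @param distances non-empty numeric vector (mm).
#' @param k_outlier,k_extreme fence multipliers.
#' @return list with `mean, median, q1, q3, iqr, outlier_pct,
#'   extreme_pct, n` (percentages in 0-100).
#' @export
distance_stats <- function(distances, k_outlier = 1.5, k_extreme = 3.0) {
  x <- as.numeric(distances)
  if (length(x) == 0L) pmri_stop("empty_data", "no distances given")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  list(mean = mean(x), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       outlier_pct = 100 * mean(x > q[3] + k_outlier * iqr),
       extreme_pct = 100 * mean(x > q[3] + k_extreme * iqr),
       n = length(x))
}

#' Convex-hull envelope of a mesh
#'
#' The tight convex envelope of the vertex cloud, used to compare
#' cortical surfaces whose local folding differs while their global
#' envelope should agree. Incremental quickhull; faces are oriented
#' outward.
#'
#' @param mesh a [trimesh()] or an n x 3 point matrix with at least 4
#'   non-coplanar points.
#' @return a [trimesh()] convex hull.
#' @export
hull_envelope <- function(mesh) {
  pts <- if (inherits(mesh, "trimesh")) mesh$vertices else as_point_matrix(mesh)
  hull <- quickhull3(pts)
  trimesh(pts[hull$vert, , drop = FALSE], hull$faces, allow_degenerate = TRUE)
}

# Incremental quickhull in 3D. Returns vertex indices used and 1-based
# faces into that index vector, outward-oriented.
quickhull3 <- function(pts) {
  n <- nrow(pts)
  if (n < 4L) pmri_stop("degenerate_geometry", "need at least 4 points")
  scale <- max(1, max(abs(pts)))
  eps <- 1e-9 * scale
  # initial simplex: extremes along x, farthest point from that segment,
  # farthest point from that triangle
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  d <- pts[i2, ] - pts[i1, ]
  v <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(v[, 2] * d[3] - v[, 3] * d[2],
              v[, 3] * d[1] - v[, 1] * d[3],
              v[, 1] * d[2] - v[, 2] * d[1])
  i3 <- which.max(row_norms(cr))
  nrm <- cross3(matrix(pts[i2, ] - pts[i1, ], 1), matrix(pts[i3, ] - pts[i1, ], 1))[1, ]
  nn <- sqrt(sum(nrm^2))
  if (nn < eps^2) pmri_stop("degenerate_geometry", "points are collinear")
  nrm <- nrm / nn
  h <- as.numeric(sweep(pts, 2, pts[i1, ]) %*% nrm)
  i4 <- which.max(abs(h))
  if (abs(h[i4]) < eps) pmri_stop("degenerate_geometry", "points are coplanar")
  simplex <- c(i1, i2, i3, i4)
  centroid <- colMeans(pts[simplex, , drop = FALSE])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- pts[f[1], ]
    nf <- cross3(matrix(pts[f[2], ] - a, 1), matrix(pts[f[3], ] - a, 1))[1, ]
    if (sum(nf * (a - centroid)) < 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  face_plane <- function(f) {
    a <- pts[f[1], ]
    nf <- cross3(matrix(pts[f[2], ] - a, 1), matrix(pts[f[3], ] - a, 1))[1, ]
    nf <- nf / max(sqrt(sum(nf^2)), 1e-300)
    c(nf, sum(nf * a))
  }
  planes <- t(apply(faces, 1, face_plane))
  alive <- rep(TRUE, nrow(faces))
  assigned <- rep(NA_integer_, n)   # face each unclaimed point is outside of
  sd_all <- pts %*% t(planes[, 1:3, drop = FALSE]) -
    matrix(planes[, 4], n, nrow(faces), byrow = TRUE)
  for (p in seq_len(n)) {
    out <- which(sd_all[p, ] > eps)
    if (length(out)) assigned[p] <- out[1]
  }
  assigned[simplex] <- NA_integer_
  repeat {
    cand <- which(!is.na(assigned) & alive[assigned])
    # re-home points whose face died
    orphans <- which(!is.na(assigned) & !alive[assigned])
    for (p in orphans) {
      sd <- planes[alive, 1:3, drop = FALSE] %*% pts[p, ] - planes[alive, 4]
      out <- which(sd > eps)
      assigned[p] <- if (length(out)) which(alive)[out[1]] else NA_integer_
    }
    cand <- which(!is.na(assigned))
    if (!length(cand)) break
    # farthest outside point from its face
    dd <- vapply(cand, function(p) {
      f <- assigned[p]
      sum(planes[f, 1:3] * pts[p, ]) - planes[f, 4]
    }, 0.0)
    p <- cand[which.max(dd)]
    # visible faces
    sd <- planes[, 1:3, drop = FALSE] %*% pts[p, ] - planes[, 4]
    vis <- which(alive & sd > eps)
    if (!length(vis)) { assigned[p] <- NA_integer_; next }
    # horizon: edges of visible faces shared with a live non-visible face
    ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
    edges <- rbind(cbind(faces[vis, 1], faces[vis, 2]),
                   cbind(faces[vis, 2], faces[vis, 3]),
                   cbind(faces[vis, 3], faces[vis, 1]))
    keys <- ek(edges[, 1], edges[, 2])
    horizon <- edges[keys %in% names(which(table(keys) == 1)), , drop = FALSE]
    alive[vis] <- FALSE
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1, orient))
    newp <- t(apply(newf, 1, face_plane))
    faces <- rbind(faces, newf)
    planes <- rbind(planes, newp)
    alive <- c(alive, rep(TRUE, nrow(newf)))
    assigned[p] <- NA_integer_
  }
  faces <- faces[alive, , drop = FALSE]
  vert <- sort(unique(as.vector(faces)))
  remap <- integer(n)
  remap[vert] <- seq_along(vert)
  list(vert = vert,
       faces = matrix(remap[faces], ncol = 3))
}

#' Signed volume of a closed mesh
#' @param mesh a closed, consistently oriented [trimesh()].
#' @return volume in mm^3 (positive for outward orientation).
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c3))) / 6
}
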