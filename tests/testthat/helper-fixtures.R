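# Shared fixtures and independent oracles. Meshes are kept small (low
# subdivision, coarse volumes) so the suite stays fast; oracles are
# deliberately naive re-implementations independent of the package's
# compiled code paths.

test_spec <- function(...) {
  synth_spec(mesh_subdivision = 2L, volume_shape = c(24L, 24L, 24L),
             volume_spacing = 8, ...)
}

# memoized small template so repeated tests don't rebuild it
local({
  cache <- new.env(parent = emptyenv())
  small_template <<- function(level = 2L) {
    key <- paste0("t", level)
    if (is.null(cache[[key]]))
      cache[[key]] <- make_template(synth_spec(mesh_subdivision = level,
                                               volume_shape = c(24L, 24L, 24L),
                                               volume_spacing = 8))
    cache[[key]]
  }
})

unit_sphere_mesh <- function(level = 2L, radius = 1) {
  s <- icosphere(level)
  trimesh(s$vertices * radius, s$faces)
}

# --- independent geometry oracles (pure R, brute force) ---

# closest point on one triangle by constrained 2D minimization over
# barycentric coordinates (dense grid refine); accurate to ~1e-9 via
# projection formula instead of grid: solve the quadratic program by
# case analysis on the unconstrained minimizer.
oracle_point_tri_dist <- function(p, a, b, c) {
  e0 <- b - a; e1 <- c - a; d <- a - p
  aa <- sum(e0 * e0); bb <- sum(e0 * e1); cc <- sum(e1 * e1)
  dd <- sum(e0 * d); ee <- sum(e1 * d)
  det <- aa * cc - bb * bb
  s <- bb * ee - cc * dd; t <- bb * dd - aa * ee
  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) { # region 4
        if (dd < 0) { t <- 0; s <- min(max(-dd / aa, 0), 1) }
        else { s <- 0; t <- min(max(-ee / cc, 0), 1) }
      } else { s <- 0; t <- min(max(-ee / cc, 0), 1) }
    } else if (t < 0) { t <- 0; s <- min(max(-dd / aa, 0), 1) }
    else { inv <- 1 / det; s <- s * inv; t <- t * inv }
  } else {
    if (s < 0) {
      tmp0 <- bb + dd; tmp1 <- cc + ee
      if (tmp1 > tmp0) {
        numer <- tmp1 - tmp0; denom <- aa - 2 * bb + cc
        s <- min(max(numer / denom, 0), 1); t <- 1 - s
      } else { s <- 0; t <- min(max(-ee / cc, 0), 1) }
    } else if (t < 0) {
      tmp0 <- bb + ee; tmp1 <- aa + dd
      if (tmp1 > tmp0) {
        numer <- tmp1 - tmp0; denom <- aa - 2 * bb + cc
        t <- min(max(numer / denom, 0), 1); s <- 1 - t
      } else { t <- 0; s <- min(max(-dd / aa, 0), 1) }
    } else {
      numer <- (cc + ee) - (bb + dd); denom <- aa - 2 * bb + cc
      s <- min(max(numer / denom, 0), 1); t <- 1 - s
    }
  }
  q <- a + s * e0 + t * e1
  sqrt(sum((p - q)^2))
}

oracle_mesh_dist <- function(points, mesh) {
  apply(points, 1, function(p) {
    min(apply(mesh$faces, 1, function(f) {
      oracle_point_tri_dist(p, mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                            mesh$vertices[f[3], ])
    }))
  })
}

# Moller-Trumbore in plain R; returns all positive ray parameters
oracle_ray_hits <- function(origin, dir, mesh) {
  ts <- apply(mesh$faces, 1, function(f) {
    a <- mesh$vertices[f[1], ]; b <- mesh$vertices[f[2], ]; c <- mesh$vertices[f[3], ]
    e1 <- b - a; e2 <- c - a
    pv <- c(dir[2] * e2[3] - dir[3] * e2[2], dir[3] * e2[1] - dir[1] * e2[3],
            dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) return(NA_real_)
    tv <- origin - a
    u <- sum(tv * pv) / det
    if (u < -1e-9 || u > 1 + 1e-9) return(NA_real_)
    qv <- c(tv[2] * e1[3] - tv[3] * e1[2], tv[3] * e1[1] - tv[1] * e1[3],
            tv[1] * e1[2] - tv[2] * e1[1])
    v <- sum(dir * qv) / det
    if (v < -1e-9 || u + v > 1 + 1e-9) return(NA_real_)
    sum(e2 * qv) / det
  })
  ts <- ts[!is.na(ts) & ts > 1e-9]
  ts
}

# random rotation matrix from QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# well-separated random points in a box (rejection on minimum spacing)
separated_points <- function(n, lo = -100, hi = 100, min_dist = 6) {
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- matrix(runif(3 * 2 * n, lo, hi), ncol = 3)
    for (i in seq_len(nrow(cand))) {
      if (nrow(pts) == 0 ||
          min(sqrt(rowSums(sweep(pts, 2, cand[i, ])^2))) > min_dist) {
        pts <- rbind(pts, cand[i, ])
        if (nrow(pts) == n) break
      }
    }
  }
  pts
}

# dense pseudo-inverse solve of the regularized control-point system,
# independent of the package solver
oracle_tps_solve <- function(source, destination, kernel = "r", lambda = 1e-10) {
  n <- nrow(source)
  d2 <- outer(rowSums(source^2), rowSums(source^2), "+") -
    2 * tcrossprod(source)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  k <- switch(kernel, r = r, r3 = r^3,
              r2logr = ifelse(r > 0, r^2 * log(r), 0))
  k <- k + lambda * diag(n)
  p <- cbind(source, 1)
  l <- rbind(cbind(k, p), cbind(t(p), matrix(0, 4, 4)))
  q <- rbind(destination, matrix(0, 4, 3))
  sv <- svd(l)
  pos <- sv$d > max(sv$d) * 1e-14
  pinv <- sv$v[, pos] %*% (t(sv$u[, pos]) / sv$d[pos])
  pinv %*% q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
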