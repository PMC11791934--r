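## Synthetic head phantoms: nested ellipsoidal surfaces with a matching
## intensity volume, ground-truth-deformed "subjects", and realistic
## digitization clouds (noise, standoff, masked patches, outliers).

#' Specification for synthetic head generation
#'
#' Defaults emulate an adult head: scalp semi-axes 95/80/100 mm
#' (left-right, front-back half, up-down), shells offset 6/10/14 mm
#' inward for outer skull / inner skull / brain, digitizer noise
#' STD 0.94 mm and a 2-mm stylus standoff.
#'
#' @param scalp_semiaxes length-3 ellipsoid semi-axes (mm).
#' @param shell_offsets inward offsets for outer skull, inner skull,
#'   brain (mm, strictly increasing).
#' @param mesh_subdivision icosphere subdivision level.
#' @param volume_shape length-3 voxel counts of the intensity volume.
#' @param volume_spacing isotropic voxel size (mm).
#' @param deform_mode `"none"`, `"affine"`, `"harmonic"`, or `"tps"`.
#' @param deform_amplitude_mm maximum surface displacement for the
#'   non-affine modes.
#' @param noise_std_mm isotropic Gaussian digitization noise STD.
#' @param n_points number of digitization points to sample.
#' @param coverage_mask optional list `(direction, angle_deg)`: a
#'   spherical cap (seen from the head center) excluded from digitization.
#' @param outlier_frac fraction of digitization points replaced by
#'   outliers (0 to 0.2).
#' @param outlier_dist_mm outward displacement of outlier points.
#' @param standoff_mm stylus standoff applied along outward normals.
#' @param seed integer driving all randomness.
#' @return an object of class `"synth_spec"`.
#' @export
synth_spec <- function(scalp_semiaxes = c(95, 80, 100),
                       shell_offsets = c(6, 10, 14),
                       mesh_subdivision = 4L,
                       volume_shape = c(64L, 64L, 64L),
                       volume_spacing = 3,
                       deform_mode = "none",
                       deform_amplitude_mm = 8,
                       noise_std_mm = 0.94,
                       n_points = 200L,
                       coverage_mask = NULL,
                       outlier_frac = 0,
                       outlier_dist_mm = 30,
                       standoff_mm = 2,
                       seed = 1L) {
  if (any(diff(shell_offsets) <= 0))
    pmri_stop("invalid_spec", "shell_offsets must be strictly increasing")
  if (outlier_frac < 0 || outlier_frac > 0.2)
    pmri_stop("invalid_spec", "outlier_frac must be in [0, 0.2]")
  if (deform_amplitude_mm < 0)
    pmri_stop("invalid_spec", "deform_amplitude_mm must be >= 0")
  structure(list(scalp_semiaxes = scalp_semiaxes,
                 shell_offsets = shell_offsets,
                 mesh_subdivision = as.integer(mesh_subdivision),
                 volume_shape = as.integer(volume_shape),
                 volume_spacing = volume_spacing,
                 deform_mode = match.arg(deform_mode,
                                         c("none", "affine", "harmonic", "tps")),
                 deform_amplitude_mm = deform_amplitude_mm,
                 noise_std_mm = noise_std_mm,
                 n_points = as.integer(n_points),
                 coverage_mask = coverage_mask,
                 outlier_frac = outlier_frac,
                 outlier_dist_mm = outlier_dist_mm,
                 standoff_mm = standoff_mm,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Icosphere mesh
#'
#' Unit sphere obtained by subdividing an icosahedron `level` times and
#' reprojecting to the sphere (level 4 gives 2562 vertices / 5120 faces,
#' the tessellation conventionally used for head surfaces).
#'
#' @param level subdivision level (>= 0).
#' @return a [trimesh()] on the unit sphere, outward-oriented faces.
#' @export
icosphere <- function(level = 4L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / row_norms(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(level)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    e1 <- edge_key(f[, 1], f[, 2])
    e2 <- edge_key(f[, 2], f[, 3])
    e3 <- edge_key(f[, 3], f[, 1])
    keys <- unique(c(e1, e2, e3))
    ab <- do.call(rbind, strsplit(keys, " "))
    ia <- as.integer(ab[, 1]); ib <- as.integer(ab[, 2])
    mid <- (v[ia, , drop = FALSE] + v[ib, , drop = FALSE]) / 2
    mid <- mid / row_norms(mid)
    midx <- nrow(v) + seq_along(keys)
    names(midx) <- keys
    v <- rbind(v, mid)
    m1 <- midx[e1]; m2 <- midx[e2]; m3 <- midx[e3]
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
  }
  trimesh(v, f)
}

ellipsoid_mesh <- function(semiaxes, level) {
  s <- icosphere(level)
  trimesh(sweep(s$vertices, 2, semiaxes, `*`), s$faces)
}

#' Generate a synthetic template bundle
#'
#' Builds nested ellipsoidal scalp / outer-skull / inner-skull / brain
#' surfaces, fiducials on the scalp (nasion at the front pole, LPA/RPA at
#' the lateral poles, so the bundle is already in its head frame), and an
#' intensity volume with one distinct value per shell plus a matching
#' label volume.
#'
#' @param spec a [synth_spec()].
#' @return a template bundle: list with `surfaces` (named [trimesh()]
#'   list), `volumes` (named [volume_image()] list), `fiducials`.
#' @export
make_template <- function(spec = synth_spec()) {
  ax <- spec$scalp_semiaxes
  shells <- list(scalp = ax,
                 outer_skull = ax - spec$shell_offsets[1],
                 inner_skull = ax - spec$shell_offsets[2],
                 brain = ax - spec$shell_offsets[3])
  surfaces <- lapply(shells, ellipsoid_mesh, level = spec$mesh_subdivision)
  # snap the analytic fiducial positions onto the faceted scalp so they
  # lie exactly on the surface; the rays are axis-aligned, so the snapped
  # points stay on their axes and the bundle remains in its head frame
  fidm <- radial_project(rbind(c(0, ax[2], 0), c(-ax[1], 0, 0), c(ax[1], 0, 0)),
                         surfaces$scalp, origin = c(0, 0, 0))$points
  fids <- fiducials(nasion = fidm[1, ], lpa = fidm[2, ], rpa = fidm[3, ],
                    frame = "head")
  dm <- spec$volume_shape
  sp <- spec$volume_spacing
  aff <- diag(c(sp, sp, sp, 1))
  aff[1:3, 4] <- -sp * (dm - 1) / 2   # grid centered on the head
  g <- lapply(1:3, function(k) (seq_len(dm[k]) - 1) * sp + aff[k, 4])
  xyz <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
  # normalized radius per shell: <= 1 means inside that shell
  lab <- integer(nrow(xyz))
  for (i in seq_along(shells)) {
    r <- sqrt(rowSums(sweep(xyz, 2, shells[[i]], `/`)^2))
    lab[r <= 1] <- i          # innermost shell wins (applied outside-in)
  }
  labels <- array(lab, dm)
  intens <- array(c(0, 90, 30, 60, 110)[lab + 1L], dm)  # T1-like contrast
  list(surfaces = surfaces,
       volumes = list(T1 = volume_image(intens, aff, "intensity"),
                      aseg = volume_image(labels, aff, "label")),
       fiducials = fids)
}

# Smooth direction field used by the harmonic deformation: a random
# (seeded) combination of low-order real spherical harmonics on the unit
# direction n, tapered smoothly to zero below the fiducial-plane
# latitude. The taper confines the shape variation to the cranial vault
# -- the region scalp digitization observes and template warping aims to
# individualize -- so ground truth is recoverable in principle and the
# recovery experiment isolates engine error from coverage error (which
# the masked-patch experiment probes separately).
harmonic_field <- function(coef) {
  force(coef)
  function(n) {
    x <- n[, 1]; y <- n[, 2]; z <- n[, 3]
    # head-shape variation is dominantly bilaterally symmetric (the
    # assumption sagittal-mirror densification rests on); the x-odd
    # terms carry a deliberately small residual asymmetry
    g <- coef[1] * (3 * z^2 - 1) / 2 +
      coef[2] * (x^2 - y^2) +
      coef[4] * y * z +
      0.15 * (coef[3] * x * z + coef[5] * x * y)
    # smoothstep over latitudes 0..0.35: the field vanishes at and below
    # the fiducial plane, where no digitization point can ever land
    s <- pmin(pmax(z / 0.35, 0), 1)
    g * s * s * (3 - 2 * s)
  }
}

#' Deform a template into a synthetic subject with known ground truth
#'
#' Applies a smooth deformation of the requested mode to every surface,
#' the fiducials, and the volumes, and returns the exact deformation as a
#' function so downstream fits can be judged against ground truth.
#'
#' Modes: `"affine"` draws a rotation (<= 10 degrees), anisotropic scale
#' in 0.9-1.1 and translation (<= 5 mm); `"harmonic"` displaces points
#' radially by a smooth spherical-harmonic field scaled so the maximum
#' scalp-vertex displacement equals `deform_amplitude_mm` (the field
#' grows linearly with radius, so the head interior deforms consistently
#' and the map is exactly invertible along rays); `"tps"` uses a random
#' smooth thin-plate warp of the same amplitude.
#'
#' @param template a bundle from [make_template()].
#' @param spec a [synth_spec()] with `deform_mode != "none"`.
#' @return list `(bundle, ground_truth, ground_truth_inverse)`; the two
#'   functions map n x 3 matrices forward/backward.
#' @export
make_subject <- function(template, spec) {
  if (spec$deform_mode == "none")
    pmri_stop("invalid_spec", "make_subject requires deform_mode != 'none'")
  scalp_v <- template$surfaces$scalp$vertices
  if (spec$deform_mode == "affine") {
    par <- with_seed(spec$seed, {
      ang <- runif(3, -10, 10) * pi / 180
      sc <- runif(3, 0.9, 1.1)
      tr <- runif(3, -5, 5)
      list(ang = ang, sc = sc, tr = tr)
    })
    rx <- rot3(1, par$ang[1]); ry <- rot3(2, par$ang[2]); rz <- rot3(3, par$ang[3])
    a <- (rz %*% ry %*% rx) %*% diag(par$sc)
    gt <- function(p) sweep(as_point_matrix(p) %*% t(a), 2, -par$tr)
    ainv <- solve(a)
    gti <- function(p) sweep(as_point_matrix(p), 2, par$tr) %*% t(ainv)
  } else if (spec$deform_mode == "harmonic") {
    # Radial vault deformation: each point moves along its ray from the
    # head center by a smooth spherical-harmonic function of direction,
    # scaled so the maximum scalp-vertex displacement equals
    # deform_amplitude_mm. A radial field is what scalp digitization can
    # actually identify (control-point pairing is itself radial), so
    # recovery error measures the engine, not an unobservable tangential
    # null space; mode "affine" exercises global linear variation and
    # mode "tps" generic smooth warps instead.
    coef <- with_seed(spec$seed, runif(5, -1, 1))
    gfun <- harmonic_field(coef)
    rref <- mean(row_norms(scalp_v))
    rn <- row_norms(scalp_v)
    dirs <- scalp_v / rn
    # displacement of a scalp vertex is (r/rref)*scale*g(n); normalize on
    # the actual vertices so the max equals the requested amplitude
    scale <- spec$deform_amplitude_mm / max(abs(rn / rref * gfun(dirs)))
    # map p -> p * (1 + scale*g(n)/rref): constant factor along each ray,
    # hence exactly invertible by division
    fac_of <- function(p) {
      r <- row_norms(p)
      ok <- r > 1e-12
      fac <- rep(1, nrow(p))
      fac[ok] <- 1 + scale * gfun(p[ok, , drop = FALSE] / r[ok]) / rref
      fac
    }
    gt <- function(p) {
      p <- as_point_matrix(p)
      fac <- fac_of(p)
      if (any(fac <= 0)) pmri_stop("fold_error", "deformation folds the head")
      p * fac
    }
    gti <- function(p) {
      p <- as_point_matrix(p)
      p / fac_of(p)
    }
  } else {  # tps: random smooth bump warp of the stated amplitude
    ctrl <- with_seed(spec$seed, {
      idx <- sample.int(nrow(scalp_v), 12L)
      list(idx = idx, d = matrix(rnorm(36), 12, 3))
    })
    src <- rbind(scalp_v[ctrl$idx, , drop = FALSE], c(0, 0, 0))
    disp <- ctrl$d / max(row_norms(ctrl$d)) * spec$deform_amplitude_mm
    fw <- tps_fit(src, src + rbind(disp, 0), lambda_init = 1e-8)
    gt <- function(p) predict(fw, p)
    inv <- build_inverse_warp(fw)
    gti <- function(p) predict(inv, p)
  }
  surfaces <- lapply(template$surfaces, function(m) {
    out <- trimesh(gt(m$vertices), m$faces, allow_degenerate = TRUE)
    if (sum(rowSums(face_normals(m) * face_normals(out)) < 0) > 0)
      pmri_stop("fold_error", "deformation folds a surface")
    out
  })
  fm <- gt(fiducial_matrix(template$fiducials))
  fids <- fiducials(fm[1, ], fm[2, ], fm[3, ], frame = "head")
  volumes <- lapply(template$volumes, function(v) {
    dm <- dim(v$data)
    g <- lapply(1:3, function(k) (seq_len(dm[k]) - 1))
    ijk <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
    world <- voxel_to_world(v, ijk)
    src <- gti(world)
    vox <- world_to_voxel(v, src)
    interp <- if (v$role == "label") "nearest" else "trilinear"
    volume_image(array(sample_volume_vox(v, vox, interp), dm), v$affine, v$role)
  })
  list(bundle = list(surfaces = surfaces, volumes = volumes, fiducials = fids),
       ground_truth = gt, ground_truth_inverse = gti)
}

rot3 <- function(axis, ang) {
  c0 <- cos(ang); s0 <- sin(ang)
  m <- diag(3)
  ij <- setdiff(1:3, axis)
  m[ij[1], ij[1]] <- c0; m[ij[2], ij[2]] <- c0
  m[ij[1], ij[2]] <- -s0; m[ij[2], ij[1]] <- s0
  m
}

#' Sample a synthetic digitization cloud from a scalp surface
#'
#' Approximately area-uniform sampling (face-area-weighted triangle draw
#' plus barycentric coordinates) of points on the scalp above the
#' fiducial plane, optionally excluding a spherical-cap patch, then
#' offset by the stylus standoff along outward normals, perturbed by
#' isotropic Gaussian noise, with a fraction replaced by outward
#' outliers.
#'
#' @param scalp subject scalp [trimesh()].
#' @param fids subject [fiducials()] (define the plane; returned
#'   unchanged).
#' @param spec a [synth_spec()]; uses `n_points`, `noise_std_mm`,
#'   `standoff_mm`, `coverage_mask`, `outlier_frac`, `outlier_dist_mm`,
#'   `seed`.
#' @return list `(points, fiducials)`.
#' @export
sample_digitization <- function(scalp, fids, spec = synth_spec()) {
  n_target <- spec$n_points
  ctr <- colMeans(scalp$vertices)
  mask <- spec$coverage_mask
  if (!is.null(mask)) {
    mdir <- as.numeric(mask$direction)
    mdir <- mdir / sqrt(sum(mdir^2))
    cos_th <- cos(mask$angle_deg * pi / 180)
  }
  with_seed(spec$seed, {
    a <- scalp$vertices[scalp$faces[, 1], , drop = FALSE]
    b <- scalp$vertices[scalp$faces[, 2], , drop = FALSE]
    c3 <- scalp$vertices[scalp$faces[, 3], , drop = FALSE]
    area <- 0.5 * row_norms(cross3(b - a, c3 - a))
    pts <- matrix(0, 0, 3)
    nrm <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(pts) < n_target) {
      tries <- tries + 1L
      if (tries > 200L)
        pmri_stop("coverage_error", "coverage mask excludes too much of the scalp")
      m <- max(2L * n_target, 64L)
      fi <- sample.int(nrow(scalp$faces), m, replace = TRUE, prob = area)
      u <- runif(m); v <- runif(m)
      flip <- u + v > 1
      u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
      p <- a[fi, , drop = FALSE] * (1 - u - v) +
        b[fi, , drop = FALSE] * u + c3[fi, , drop = FALSE] * v
      fn <- face_normals(scalp)[fi, , drop = FALSE]
      out_sign <- sign(rowSums(fn * sweep(p, 2, ctr)))
      fn <- fn * ifelse(out_sign == 0, 1, out_sign)
      keep <- fiducial_plane_distances(fids, p, toward = ctr + c(0, 0, 1e6)) > 0
      if (!is.null(mask)) {
        d <- sweep(p, 2, ctr)
        d <- d / row_norms(d)
        keep <- keep & (d %*% mdir < cos_th)
      }
      pts <- rbind(pts, p[keep, , drop = FALSE])
      nrm <- rbind(nrm, fn[keep, , drop = FALSE])
      if (tries > 3L && nrow(pts) < 0.1 * tries * n_target)
        pmri_stop("coverage_error", "coverage mask excludes too much of the scalp")
    }
    pts <- pts[seq_len(n_target), , drop = FALSE]
    nrm <- nrm[seq_len(n_target), , drop = FALSE]
    pts <- pts + nrm * spec$standoff_mm
    if (spec$noise_std_mm > 0)
      pts <- pts + matrix(rnorm(3 * n_target, sd = spec$noise_std_mm),
                          n_target, 3)
    n_out <- round(spec$outlier_frac * n_target)
    if (n_out > 0) {
      oi <- sample.int(n_target, n_out)
      pts[oi, ] <- pts[oi, ] + nrm[oi, , drop = FALSE] * spec$outlier_dist_mm
    }
    list(points = pts, fiducials = fids)
  })
}
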