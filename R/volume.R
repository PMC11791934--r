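## Volumetric images: 3D intensity/label arrays with a voxel-to-world
## affine (RAS, mm), sampling, and pull-back resampling through an
## inverse TPS warp.

#' Volumetric image
#'
#' @param data 3D numeric array of intensities or integer labels.
#' @param affine 4 x 4 voxel-to-world matrix (RAS mm, 0-based voxel
#'   indices).
#' @param role `"intensity"` (trilinear resampling) or `"label"` (nearest
#'   neighbor).
#' @return an object of class `"volume_image"`.
#' @export
volume_image <- function(data, affine = diag(4), role = c("intensity", "label")) {
  role <- match.arg(role)
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    pmri_stop("invalid_volume", "data must be a 3D array")
  if (!all(is.finite(data)))
    pmri_stop("invalid_volume", "data contains non-finite values")
  affine <- matrix(as.numeric(affine), 4, 4)
  if (!all(is.finite(affine)) || abs(det(affine[1:3, 1:3])) < 1e-12)
    pmri_stop("invalid_volume", "voxel-to-world affine is not invertible")
  structure(list(data = data, affine = affine, role = role),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("volume_image: %s, %s voxels, spacing ~%.3g mm\n",
              x$role, paste(dim(x$data), collapse = " x "),
              mean(sqrt(colSums(x$affine[1:3, 1:3]^2)))))
  invisible(x)
}

# world coordinates of 0-based voxel indices (n x 3)
voxel_to_world <- function(vol, ijk) {
  cbind(ijk, 1) %*% t(vol$affine[1:3, , drop = FALSE])
}

world_to_voxel <- function(vol, xyz) {
  cbind(xyz, 1) %*% t(solve(vol$affine)[1:3, , drop = FALSE])
}

# Sample the volume at continuous 0-based voxel coordinates.
# Out-of-field points give 0.
sample_volume_vox <- function(vol, ijk, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  dm <- dim(vol$data)
  n <- nrow(ijk)
  out <- numeric(n)
  if (interp == "nearest") {
    r <- round(ijk)
    ok <- r[, 1] >= 0 & r[, 1] <= dm[1] - 1 &
          r[, 2] >= 0 & r[, 2] <= dm[2] - 1 &
          r[, 3] >= 0 & r[, 3] <= dm[3] - 1
    if (any(ok)) {
      idx <- r[ok, 1] + dm[1] * (r[ok, 2] + dm[2] * r[ok, 3]) + 1
      out[ok] <- vol$data[idx]
    }
    return(out)
  }
  f <- floor(ijk)
  t <- ijk - f
  ok <- f[, 1] >= -1 & f[, 1] <= dm[1] - 1 &
        f[, 2] >= -1 & f[, 2] <= dm[2] - 1 &
        f[, 3] >= -1 & f[, 3] <= dm[3] - 1
  acc <- numeric(sum(ok))
  fo <- f[ok, , drop = FALSE]; to <- t[ok, , drop = FALSE]
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ci <- fo[, 1] + dx; cj <- fo[, 2] + dy; ck <- fo[, 3] + dz
    w <- (if (dx == 1) to[, 1] else 1 - to[, 1]) *
         (if (dy == 1) to[, 2] else 1 - to[, 2]) *
         (if (dz == 1) to[, 3] else 1 - to[, 3])
    inb <- ci >= 0 & ci <= dm[1] - 1 & cj >= 0 & cj <= dm[2] - 1 &
           ck >= 0 & ck <= dm[3] - 1 & w > 0
    if (any(inb)) {
      idx <- ci[inb] + dm[1] * (cj[inb] + dm[2] * ck[inb]) + 1
      acc[inb] <- acc[inb] + w[inb] * vol$data[idx]
    }
  }
  out[ok] <- acc
  out
}

#' Resample a volume through a TPS warp
#'
#' Pull-back resampling: the intensity at each output voxel is the input
#' volume sampled at `inverse(world(voxel))`, so the output occupies the
#' same grid as the input but shows the warped anatomy. Intensity volumes
#' are interpolated trilinearly, label volumes by nearest neighbor (no
#' new label values can appear). Voxels mapping outside the field of view
#' are set to 0.
#'
#' @param warp a `"tps"` forward warp (template to subject).
#' @param vol a [volume_image()] with invertible affine.
#' @param interp `"trilinear"`, `"nearest"`, or `NULL` to pick by the
#'   volume's role.
#' @param inverse optional precomputed inverse warp (a `"tps"`); computed
#'   via [build_inverse_warp()] when missing.
#' @param block voxels processed per block.
#' @return a [volume_image()] on the input grid.
#' @export
warp_volume <- function(warp, vol, interp = NULL, inverse = NULL,
                        block = 50000L) {
  stopifnot(inherits(vol, "volume_image"))
  if (is.null(interp))
    interp <- if (vol$role == "label") "nearest" else "trilinear"
  interp <- match.arg(interp, c("trilinear", "nearest"))
  if (is.null(inverse)) inverse <- build_inverse_warp(warp)
  dm <- dim(vol$data)
  nvox <- prod(dm)
  out <- numeric(nvox)
  inv_aff <- solve(vol$affine)[1:3, , drop = FALSE]
  for (start in seq(1L, nvox, by = block)) {
    idx <- start:min(start + block - 1L, nvox)
    lin <- idx - 1L
    i <- lin %% dm[1]
    j <- (lin %/% dm[1]) %% dm[2]
    k <- lin %/% (dm[1] * dm[2])
    world <- cbind(i, j, k, 1) %*% t(vol$affine[1:3, , drop = FALSE])
    src_world <- predict(inverse, world)
    src_vox <- cbind(src_world, 1) %*% t(inv_aff)
    out[idx] <- sample_volume_vox(vol, src_vox, interp)
  }
  arr <- array(out, dm)
  # nearest-neighbor resampling of an integer (label) volume stays integer
  if (interp == "nearest" && is.integer(vol$data)) storage.mode(arr) <- "integer"
  volume_image(arr, vol$affine, vol$role)
}
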