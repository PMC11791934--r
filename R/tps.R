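## Thin-plate-spline warp: control-point pairing, adaptively regularized
## solve of the (N+4)x(N+4) linear system, evaluation, energies, inverse.

tps_kernels <- c("r", "r2logr", "r3")

tps_kernel_eval <- function(r, kernel) {
  switch(kernel,
         r = r,
         r2logr = ifelse(r > 0, r^2 * log(r), 0),
         r3 = r^3,
         pmri_stop("invalid_kernel", sprintf("unknown kernel '%s'", kernel)))
}

# Kernel matrix between two point sets (rows of a vs rows of b).
# Distances are computed difference-first: the |a|^2+|b|^2-2ab' expansion
# loses ~sqrt(eps * scale) absolute accuracy to cancellation near r = 0,
# which would corrupt phi(r) = r at the control points themselves.
tps_kernel_matrix <- function(a, b, kernel) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2
  tps_kernel_eval(sqrt(d2), kernel)
}

#' Pair digitization points with template-scalp control points
#'
#' Radially projects conditioned head points onto the template scalp; the
#' projections are the source control points p_i and the head points
#' themselves the destinations q_i of the warp. Fiducials, when given,
#' are appended as additional pairs (their projections anchor the warp at
#' the landmarks).
#'
#' @param points n x 3 conditioned head points in the template frame (mm).
#' @param scalp template scalp [trimesh()].
#' @param origin projection-ray origin (head-frame origin by default).
#' @param fids optional [fiducials()] appended as control points.
#' @return list `(source, destination, fallback)`; `fallback` flags pairs
#'   whose projection ray missed the mesh (nearest point used).
#' @export
pair_control_points <- function(points, scalp, origin = c(0, 0, 0),
                                fids = NULL) {
  points <- as_point_matrix(points)
  if (!is.null(fids)) points <- rbind(points, fiducial_matrix(fids))
  pr <- radial_project(points, scalp, origin)
  list(source = pr$points, destination = points, fallback = pr$fallback)
}

#' Fit a 3D thin-plate-spline warp
#'
#' Solves for the warp `f(x) = a0 + a1 x + a2 y + a3 z + sum_i w_i
#' phi(||x - p_i||)` mapping source control points `p_i` onto destinations
#' `q_i`. The coefficients satisfy the `(N+4) x (N+4)` linear system
#' `L W = Q` with `L = [K + lambda I, P; P', 0]`, where `K` is the kernel
#' matrix, `P = [x y z 1]` and the zero block enforces the moment
#' conditions `sum w_i = 0`, `sum w_i p_i' = 0`.
#'
#' Regularization is adaptive: the solve starts at `lambda_init` and
#' multiplies `lambda` by `lambda_growth` until the system is stable
#' (finite solution, condition estimate below `cond_max`, relative
#' residual below 1e-8), keeping smoothing minimal while guaranteeing a
#' solvable system even for sparse or degenerate pairings.
#'
#' @param source,destination N x 3 matrices of paired control points (mm),
#'   N >= 5, source points distinct.
#' @param kernel radial basis: `"r"` (3D biharmonic, default), `"r2logr"`,
#'   or `"r3"`.
#' @param lambda_init initial regularization added to the kernel diagonal.
#' @param lambda_growth multiplicative escalation factor.
#' @param lambda_max largest lambda tried before giving up.
#' @param cond_max condition-number estimate above which the system is
#'   declared unstable.
#' @return an object of class `"tps"`: nonlinear coefficients `W` (N x 3),
#'   `affine` (4 x 3, rows = x/y/z/intercept), the source points, the
#'   kernel id, `lambda_used`, `bending_energy` (classic functional) and
#'   `residual_energy` (summed squared control-point residuals),
#'   `residual_rms`.
#' @export
tps_fit <- function(source, destination, kernel = "r",
                    lambda_init = 1e-10, lambda_growth = 10,
                    lambda_max = 1e-2, cond_max = 1e12) {
  source <- as_point_matrix(source, "source")
  destination <- as_point_matrix(destination, "destination")
  n <- nrow(source)
  if (n != nrow(destination))
    pmri_stop("invalid_control_points", "source/destination lengths differ")
  if (n < 5L)
    pmri_stop("invalid_control_points", "need at least 5 control-point pairs")
  kernel <- match.arg(kernel, tps_kernels)
  if (min(stats::dist(source)) < 1e-9)
    pmri_stop("singular_kernel", "duplicate source control points")

  sys <- tps_assemble(source, destination, kernel)
  lambda <- lambda_init
  repeat {
    l <- sys$L
    diag(l)[seq_len(n)] <- diag(l)[seq_len(n)] + lambda
    sol <- tryCatch(solve(l, sys$Q), error = function(e) NULL)
    ok <- !is.null(sol) && all(is.finite(sol))
    if (ok) {
      # two steps of iterative refinement: the LU residual at large N is
      # otherwise limited by kappa(L) * machine eps
      for (it in 1:2) {
        resid <- sys$Q - l %*% sol
        corr <- tryCatch(solve(l, resid), error = function(e) NULL)
        if (is.null(corr) || !all(is.finite(corr))) break
        sol <- sol + corr
      }
      rel <- norm(l %*% sol - sys$Q, "F") / max(norm(sys$Q, "F"), 1e-300)
      ok <- rel <= 1e-8 && kappa(l, exact = FALSE) <= cond_max
    }
    if (ok) break
    lambda <- lambda * lambda_growth
    if (lambda > lambda_max)
      pmri_stop("non_convergent_regularization",
                sprintf("no stable solve up to lambda = %g", lambda_max))
  }

  w <- sol[seq_len(n), , drop = FALSE]
  affine <- sol[n + 1:4, , drop = FALSE]
  fit <- structure(
    list(W = w, affine = affine, sources = source, kernel = kernel,
         lambda_used = lambda, n = n),
    class = "tps")
  res <- predict(fit, source) - destination
  rn2 <- rowSums(res^2)
  fit$residual_rms <- sqrt(mean(rn2))
  fit$residual_energy <- sum(rn2)
  fit$bending_energy <- sum(diag(crossprod(w, sys$K %*% w)))
  fit$destinations <- destination
  fit
}

# Assemble K, P, L, Q for the control-point system.
tps_assemble <- function(source, destination, kernel) {
  n <- nrow(source)
  k <- tps_kernel_matrix(source, source, kernel)
  diag(k) <- 0  # phi(0) = 0 exactly; the expansion suffers cancellation
  p <- cbind(source, 1)
  l <- rbind(cbind(k, p), cbind(t(p), matrix(0, 4, 4)))
  q <- rbind(destination, matrix(0, 4, 3))
  list(K = k, P = p, L = l, Q = q)
}

#' Evaluate a fitted thin-plate-spline warp
#'
#' @param object a `"tps"` fit.
#' @param newdata n x 3 matrix of points to warp (mm).
#' @param block points are processed in blocks of this size to bound the
#'   kernel-matrix memory.
#' @param ... unused.
#' @return n x 3 matrix of warped points.
#' @export
predict.tps <- function(object, newdata, block = 20000L, ...) {
  x <- as_point_matrix(newdata, "newdata")
  n <- nrow(x)
  out <- matrix(0, n, 3)
  a <- object$affine
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    xi <- x[idx, , drop = FALSE]
    u <- tps_kernel_matrix(xi, object$sources, object$kernel)
    out[idx, ] <- xi %*% a[1:3, , drop = FALSE] +
      matrix(a[4, ], length(idx), 3, byrow = TRUE) + u %*% object$W
  }
  out
}

#' @export
print.tps <- function(x, ...) {
  cat(sprintf("Thin-plate-spline warp (kernel phi = %s)\n", x$kernel))
  cat(sprintf("  control-point pairs : %d\n", x$n))
  cat(sprintf("  lambda used         : %g\n", x$lambda_used))
  cat(sprintf("  residual RMS        : %.4g mm\n", x$residual_rms))
  cat(sprintf("  bending energy      : %.4g (classic), %.4g (residual)\n",
              x$bending_energy, x$residual_energy))
  invisible(x)
}

#' @export
summary.tps <- function(object, ...) {
  res <- residuals(object)
  out <- list(kernel = object$kernel, n = object$n,
              lambda_used = object$lambda_used,
              residual_rms = object$residual_rms,
              residual_max = if (length(res)) max(res) else NA_real_,
              bending_energy = object$bending_energy,
              residual_energy = object$residual_energy,
              w_max = max(abs(object$W)))
  class(out) <- "summary.tps"
  out
}

#' @export
print.summary.tps <- function(x, ...) {
  cat(sprintf("TPS warp summary: N = %d, kernel = %s\n", x$n, x$kernel))
  cat(sprintf("  lambda = %g, residual RMS = %.4g mm (max %.4g mm)\n",
              x$lambda_used, x$residual_rms, x$residual_max))
  cat(sprintf("  bending energy %.4g, residual energy %.4g, max|w| %.4g\n",
              x$bending_energy, x$residual_energy, x$w_max))
  invisible(x)
}

#' @export
coef.tps <- function(object, ...) {
  list(W = object$W, affine = object$affine)
}

#' Control-point residual distances of a TPS fit
#' @param object a `"tps"` fit.
#' @param ... unused.
#' @return numeric vector `||f(p_i) - q_i||` (mm).
#' @export
residuals.tps <- function(object, ...) {
  if (is.null(object$destinations)) return(numeric(0))
  row_norms(predict(object, object$sources) - object$destinations)
}

#' Bending energies of a TPS warp
#'
#' Two conventions are reported: `E_residual`, the summed squared
#' distances between warped source and destination control points, and
#' `E_classic`, the classical thin-plate functional
#' `trace(W' K W)` which vanishes for purely affine warps.
#'
#' @param warp a `"tps"` fit.
#' @return named list `(E_classic, E_residual)`.
#' @export
bending_energy <- function(warp) {
  stopifnot(inherits(warp, "tps"))
  list(E_classic = warp$bending_energy, E_residual = warp$residual_energy)
}

#' Warp a surface mesh
#'
#' Applies the warp to every vertex; faces are unchanged. Faces whose
#' normal flips orientation relative to the input are counted as folds
#' (reported, not fatal).
#'
#' @param warp a `"tps"` fit.
#' @param mesh a [trimesh()] in the warp's source frame.
#' @return list `(mesh, n_flipped)`.
#' @export
warp_mesh <- function(warp, mesh) {
  v <- predict(warp, mesh$vertices)
  out <- trimesh(v, mesh$faces, allow_degenerate = TRUE)
  n0 <- face_normals(mesh)
  n1 <- face_normals(out)
  flipped <- sum(rowSums(n0 * n1) < 0)
  list(mesh = out, n_flipped = flipped)
}

#' Approximate inverse of a TPS warp
#'
#' Fits a second thin-plate spline on reversed pairs: forward-warped seed
#' points map back to the seeds. Seeds default to the warp's own source
#' control points plus a coarse lattice spanning their bounding box, so
#' the inverse is accurate over the head volume. The median round-trip
#' error `||inv(fwd(x)) - x||` over a validation lattice is attached as
#' attribute `"roundtrip_median_mm"`.
#'
#' @param warp a `"tps"` fit.
#' @param seed_points optional n x 3 seed matrix; default as described.
#' @param lattice_n lattice resolution per axis for the default seeds.
#' @param ... passed to [tps_fit()] (kernel defaults to the forward one).
#' @return a `"tps"` fit mapping warped space back to source space.
#' @export
build_inverse_warp <- function(warp, seed_points = NULL, lattice_n = 6L, ...) {
  if (is.null(seed_points)) {
    lo <- apply(warp$sources, 2, min); hi <- apply(warp$sources, 2, max)
    pad <- 0.1 * (hi - lo + 1)
    g <- lapply(1:3, function(k)
      seq(lo[k] - pad[k], hi[k] + pad[k], length.out = lattice_n))
    lattice <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
    dimnames(lattice) <- NULL
    seed_points <- rbind(warp$sources, lattice)
  }
  seed_points <- dedupe_points(seed_points, 1e-6)
  fwd <- predict(warp, seed_points)
  keep <- !duplicated(round(fwd / 1e-6))  # forward images must be distinct
  inv <- tps_fit(fwd[keep, , drop = FALSE], seed_points[keep, , drop = FALSE],
                 kernel = warp$kernel, ...)
  # round-trip audit on a 10-mm validation lattice over the seed bbox
  lo <- apply(seed_points, 2, min); hi <- apply(seed_points, 2, max)
  g <- lapply(1:3, function(k) seq(lo[k], hi[k], by = 10))
  val <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
  dimnames(val) <- NULL
  rt <- row_norms(predict(inv, predict(warp, val)) - val)
  attr(inv, "roundtrip_median_mm") <- median(rt)
  inv
}

dedupe_points <- function(points, tol) {
  points[!duplicated(round(points / tol)), , drop = FALSE]
}

#' Serialize a TPS warp to a plain-text file
#'
#' Writes kernel id, source points, coefficients, lambda and energies as
#' JSON with full double precision; [read_tps()] restores a numerically
#' identical object.
#'
#' @param warp a `"tps"` fit.
#' @param path output file path.
#' @export
write_tps <- function(warp, path) {
  stopifnot(inherits(warp, "tps"))
  obj <- list(format = "pseudomri-tps-1", kernel = warp$kernel,
              n = warp$n, lambda_used = warp$lambda_used,
              sources = warp$sources, W = warp$W, affine = warp$affine,
              destinations = warp$destinations,
              residual_rms = warp$residual_rms,
              residual_energy = warp$residual_energy,
              bending_energy = warp$bending_energy)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized TPS warp
#' @param path file written by [write_tps()].
#' @return the restored `"tps"` object.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) pmri_stop("format_error", sprintf("no such file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "pseudomri-tps-1")
    pmri_stop("format_error", "not a pseudomri TPS warp file")
  fit <- structure(
    list(W = matrix(obj$W, ncol = 3), affine = matrix(obj$affine, ncol = 3),
         sources = matrix(obj$sources, ncol = 3), kernel = obj$kernel,
         lambda_used = obj$lambda_used, n = obj$n,
         residual_rms = obj$residual_rms,
         residual_energy = obj$residual_energy,
         bending_energy = obj$bending_energy,
         destinations = if (!is.null(obj$destinations))
           matrix(obj$destinations, ncol = 3) else NULL),
    class = "tps")
  fit
}
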