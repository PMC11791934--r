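test_that("system assembly has the published block structure", {
  set.seed(81)
  src <- separated_points(12)
  sys <- pseudomri:::tps_assemble(src, src + 1, "r")
  expect_equal(dim(sys$L), c(16, 16))
  expect_equal(diag(sys$K), rep(0, 12))           # phi(0) = 0
  expect_equal(sys$L, t(sys$L))                   # symmetry
  expect_equal(sys$L[13:16, 13:16], matrix(0, 4, 4))
  expect_equal(sys$Q[13:16, ], matrix(0, 4, 3))
  expect_error(tps_fit(rbind(src, src[1, ]), rbind(src, src[1, ]) + 1),
               class = "singular_kernel")
  expect_error(tps_fit(src[1:4, ], src[1:4, ]),
               class = "invalid_control_points")
})

test_that("identity, translation and affine pairs are reproduced exactly", {
  set.seed(82)
  src <- separated_points(30)

  fit_id <- tps_fit(src, src)
  expect_lt(max(abs(fit_id$W)), 1e-9)
  expect_lt(fit_id$residual_rms, 1e-9)
  expect_lt(max(abs(fit_id$affine[1:3, ] - diag(3))), 1e-9)
  expect_lt(max(abs(fit_id$affine[4, ])), 1e-7)

  t0 <- c(4, -7, 2)
  fit_tr <- tps_fit(src, sweep(src, 2, -t0))
  expect_lt(max(abs(fit_tr$W)), 1e-9)
  probe <- matrix(rnorm(30, sd = 80), 10, 3)
  expect_lt(max(abs(predict(fit_tr, probe) - sweep(probe, 2, -t0))), 1e-6)

  a <- matrix(c(1.1, 0.1, -0.05, 0.02, 0.9, 0.07, -0.03, 0.05, 1.05), 3, 3)
  b <- c(3, -2, 5)
  fit_af <- tps_fit(src, sweep(src %*% t(a), 2, -b))
  expect_lt(max(abs(fit_af$W)), 1e-6)
  held <- matrix(runif(300, -90, 90), 100, 3)
  expect_lt(max(abs(predict(fit_af, held) - sweep(held %*% t(a), 2, -b))), 1e-6)
})

test_that("moment conditions and interpolation hold at minimal lambda", {
  set.seed(83)
  for (n in c(5, 25, 150)) {
    src <- separated_points(n)
    dst <- src + matrix(rnorm(3 * n, sd = 4), n, 3)
    fit <- tps_fit(src, dst)
    expect_lt(max(abs(colSums(fit$W))), 1e-6)
    expect_lt(max(abs(crossprod(fit$W, src))), 1e-6)
    expect_lt(max(sqrt(rowSums((predict(fit, src) - dst)^2))), 1e-6)
  }
})

test_that("solved coefficients match the dense pseudo-inverse oracle", {
  set.seed(84)
  for (n in c(10, 30, 50)) {
    src <- separated_points(n)
    dst <- src + matrix(rnorm(3 * n, sd = 5), n, 3)
    fit <- tps_fit(src, dst)
    w_oracle <- oracle_tps_solve(src, dst, lambda = fit$lambda_used)
    expect_lt(max(abs(rbind(fit$W, fit$affine) - w_oracle)), 1e-6)
  }
})

test_that("scalar and batch warp evaluation agree", {
  set.seed(85)
  src <- separated_points(20)
  fit <- tps_fit(src, src + matrix(rnorm(60, sd = 3), 20, 3))
  pts <- matrix(rnorm(3000, sd = 70), 1000, 3)
  batch <- predict(fit, pts)
  expect_equal(predict(fit, pts[137, , drop = FALSE]),
               batch[137, , drop = FALSE], tolerance = 1e-12)
  # block size must not change results
  expect_equal(predict(fit, pts, block = 64L), batch, tolerance = 1e-12)
})

test_that("residual energy is non-decreasing along the regularization path", {
  set.seed(86)
  src <- separated_points(40)
  dst <- src + matrix(rnorm(120, sd = 3), 40, 3)
  energies <- vapply(c(1e-10, 1e-6, 1e-3), function(l) {
    fit <- tps_fit(src, dst, lambda_init = l)
    expect_equal(fit$lambda_used, l)
    bending_energy(fit)$E_residual
  }, 0.0)
  expect_true(all(diff(energies) >= -1e-9))
  # identity pairs: both energies vanish
  fit_id <- tps_fit(src, src)
  be <- bending_energy(fit_id)
  expect_lt(abs(be$E_classic), 1e-9)
  expect_lt(abs(be$E_residual), 1e-9)
})

test_that("warped meshes keep faces and detect no folds for smooth warps", {
  mesh <- unit_sphere_mesh(2, radius = 95)
  set.seed(87)
  src <- separated_points(25)
  id <- tps_fit(src, src)
  wm <- warp_mesh(id, mesh)
  expect_equal(wm$mesh$faces, mesh$faces)
  expect_lt(max(abs(wm$mesh$vertices - mesh$vertices)), 1e-6)
  expect_equal(wm$n_flipped, 0)

  tr <- tps_fit(src, sweep(src, 2, -c(2, 3, -1)))
  wtr <- warp_mesh(tr, mesh)
  expect_lt(max(abs(wtr$mesh$vertices - sweep(mesh$vertices, 2, -c(2, 3, -1)))),
            1e-6)
  expect_equal(wtr$n_flipped, 0)

  # smooth synthetic warp of the scalp: no flipped faces
  on_sphere <- mesh$vertices[seq(1, nrow(mesh$vertices), by = 6), ]
  bump <- on_sphere * (1 + 0.04 * sin(on_sphere[, 1] / 30))
  sm <- tps_fit(on_sphere, bump)
  expect_equal(warp_mesh(sm, mesh)$n_flipped, 0)
})

test_that("inverse warp reproduces analytic inverses and round-trips", {
  set.seed(88)
  src <- separated_points(30)
  # affine forward -> inverse matches the analytic inverse on held-out points
  a <- diag(3) + matrix(rnorm(9, sd = 0.03), 3, 3)
  b <- c(2, -4, 1)
  fwd <- tps_fit(src, sweep(src %*% t(a), 2, -b))
  inv <- build_inverse_warp(fwd)
  held <- matrix(runif(150, -80, 80), 50, 3)
  expect_lt(max(abs(predict(inv, held) - sweep(held, 2, b) %*% t(solve(a)))),
            1e-4)

  # identity forward -> identity inverse
  idw <- build_inverse_warp(tps_fit(src, src))
  expect_lt(max(abs(predict(idw, held) - held)), 1e-6)

  # smooth small-amplitude warp: median round-trip error below 0.5 mm
  sphere <- unit_sphere_mesh(2, radius = 90)$vertices
  ctrl <- sphere[seq(1, nrow(sphere), by = 5), ]
  disp <- matrix(rnorm(length(ctrl), sd = 1.8), ncol = 3)
  disp <- disp / max(sqrt(rowSums(disp^2))) * 5
  fwd2 <- tps_fit(ctrl, ctrl + disp)
  inv2 <- build_inverse_warp(fwd2)
  expect_lt(attr(inv2, "roundtrip_median_mm"), 0.5)
})

test_that("adaptive regularization escalates to a stable finite lambda", {
  set.seed(89)
  # nearly coincident source clusters make the kernel ill-conditioned
  base <- separated_points(15)
  src <- rbind(base, base + 1e-8)
  dst <- src + matrix(rnorm(nrow(src) * 3, sd = 2), ncol = 3)
  fit <- tps_fit(src, dst)
  expect_true(is.finite(fit$lambda_used))
  expect_gt(fit$lambda_used, 1e-10)
  expect_lte(fit$lambda_used, 1e-2)
})

test_that("warp files round-trip numerically identically", {
  set.seed(90)
  src <- separated_points(25)
  fit <- tps_fit(src, src + matrix(rnorm(75, sd = 3), 25, 3))
  path <- tempfile(fileext = ".json")
  write_tps(fit, path)
  back <- read_tps(path)
  expect_identical(back$W, fit$W)
  expect_identical(back$affine, fit$affine)
  expect_identical(back$sources, fit$sources)
  expect_identical(back$lambda_used, fit$lambda_used)
  expect_identical(back$kernel, fit$kernel)
  pts <- matrix(rnorm(30, sd = 50), 10, 3)
  expect_identical(predict(back, pts), predict(fit, pts))
  expect_error(read_tps(tempfile()), class = "format_error")
})
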