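head_fids <- fiducials(c(0, 95, 0), c(-75, 0, 0), c(75, 0, 0))

test_that("fiducial-plane filter keeps exactly the points above the margin", {
  pts <- rbind(c(0, 0, 50), c(0, 0, -5), c(0, 0, -15), c(30, 40, 2))
  res <- filter_below_fiducial_plane(pts, head_fids, margin_mm = 10)
  expect_equal(res$kept, c(1, 2, 4))
  expect_equal(res$dropped, 3)

  # all-above cloud passes unchanged
  above <- cbind(rnorm(50, sd = 30), rnorm(50, sd = 30), runif(50, 5, 90))
  expect_equal(nrow(filter_below_fiducial_plane(above, head_fids, 10)$points), 50)

  # oracle: per-point plane equation (head frame plane is z = 0)
  set.seed(51)
  cloud <- cbind(rnorm(200, sd = 50), rnorm(200, sd = 50), rnorm(200, 30, 40))
  res2 <- filter_below_fiducial_plane(cloud, head_fids, 10)
  expect_identical(res2$kept, which(cloud[, 3] > -10))
})

test_that("outlier rejection enforces the 2-10% band and the MAD rule", {
  scalp <- unit_sphere_mesh(2, radius = 100)
  cfg <- conditioning_config()

  # all points on the scalp: exactly the 2% minimum is removed
  on <- scalp$vertices[sample(nrow(scalp$vertices), 100), ]
  res <- reject_scalp_outliers(on, scalp, cfg)
  expect_equal(length(res$dropped), 2)

  # one gross outlier is always among the removals
  pts <- rbind(on[1:99, ], c(0, 0, 160))
  res2 <- reject_scalp_outliers(pts, scalp, cfg)
  expect_true(100 %in% res2$dropped)

  # oracle: direct re-application of the stated rule on random distances
  set.seed(61)
  for (trial in 1:20) {
    n <- sample(20:200, 1)
    r <- 100 + c(rnorm(n - 3, sd = 1), runif(3, 5, 40))  # tail of far points
    dirs <- matrix(rnorm(3 * n), n, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- dirs * r
    res3 <- reject_scalp_outliers(pts, scalp, cfg)
    d <- point_mesh_distances(pts, scalp)
    n_min <- ceiling(0.02 * n); n_cap <- floor(0.10 * n)
    ord <- order(d, seq_len(n), decreasing = TRUE)
    drop <- ord[seq_len(n_min)]
    thr <- median(d) + 3 * mad(d)
    extra <- setdiff(ord[d[ord] > thr], drop)
    if (length(extra) && n_min < n_cap)
      drop <- c(drop, extra[seq_len(min(length(extra), n_cap - n_min))])
    expect_setequal(res3$dropped, drop)
    frac <- length(res3$dropped) / n
    expect_gte(frac, 0.02 - 1e-12)
    expect_lte(frac, 0.10 + 1e-12)
  }

  expect_error(reject_scalp_outliers(on[1:5, ], scalp, cfg),
               class = "too_few_points")
})

test_that("sagittal mirroring doubles density up to dedupe and is an involution", {
  set.seed(71)
  pts <- cbind(runif(100, 5, 70), rnorm(100, sd = 40), runif(100, 10, 90))
  md <- mirror_densify(pts, head_fids, dedupe_tol_mm = 1)
  expect_equal(nrow(md$points), 200)
  expect_equal(md$source_index, c(1:100, 1:100))

  # point on the sagittal plane contributes one point
  onplane <- matrix(c(0, 40, 60), 1, 3)
  expect_equal(nrow(mirror_densify(onplane, head_fids, 1)$points), 1)

  # mirror symmetry: distance-to-plane multiset is balanced across sides
  out <- md$points
  expect_equal(sort(out[out[, 1] > 0, 1]), sort(-out[out[, 1] < 0, 1]),
               tolerance = 1e-12)

  # involution: mirroring twice adds nothing more
  md2 <- mirror_densify(md$points, head_fids, dedupe_tol_mm = 1)
  expect_equal(nrow(md2$points), nrow(md$points))
})

test_that("inward shift moves points exactly shift_mm toward the origin", {
  expect_equal(inward_shift(matrix(c(0, 0, 100), 1, 3), shift_mm = 1.5),
               matrix(c(0, 0, 98.5), 1, 3), tolerance = 1e-12)
  pts <- matrix(rnorm(90, sd = 60), 30, 3)
  expect_identical(inward_shift(pts, shift_mm = 0), pts)
  r0 <- sqrt(rowSums(pts^2))
  shifted <- inward_shift(pts, shift_mm = 1.2)
  expect_equal(sqrt(rowSums(shifted^2)), r0 - 1.2, tolerance = 1e-9)
  expect_error(inward_shift(matrix(c(0.5, 0, 0), 1, 3), shift_mm = 1.5),
               class = "degenerate_direction")
})

test_that("full conditioning composes the stages with the spec'd branches", {
  tmpl <- small_template()
  scalp <- tmpl$surfaces$scalp
  fids <- tmpl$fiducials
  spec <- test_spec(n_points = 150, seed = 5)
  dig <- sample_digitization(scalp, fids, spec)
  cfg <- conditioning_config()

  # 150 clean points: no densification, no cap; only the 2% floor bites
  res <- condition_digitization(dig$points, fids, scalp, cfg, seed = 1)
  expect_false(res$report$densified)
  expect_equal(res$report$after_outlier_rejection,
               res$report$after_plane_filter -
                 ceiling(0.02 * res$report$after_plane_filter))
  expect_equal(nrow(res$points), res$report$after_downsampling)

  # sparse cloud triggers mirroring
  dig40 <- sample_digitization(scalp, fids, test_spec(n_points = 40, seed = 6))
  res40 <- condition_digitization(dig40$points, fids, scalp, cfg, seed = 1)
  expect_true(res40$report$densified)
  expect_gt(nrow(res40$points), 60)

  # dense cloud capped at exactly n_max
  dig1k <- sample_digitization(scalp, fids, test_spec(n_points = 1000, seed = 7))
  res1k <- condition_digitization(dig1k$points, fids, scalp, cfg, seed = 1)
  expect_equal(nrow(res1k$points), 300)

  # determinism
  resb <- condition_digitization(dig$points, fids, scalp, cfg, seed = 1)
  expect_identical(res$points, resb$points)
})
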