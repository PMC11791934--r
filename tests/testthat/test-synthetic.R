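test_that("template bundles are nested, labeled, and carry on-scalp fiducials", {
  tmpl <- small_template()
  expect_named(tmpl$surfaces, c("scalp", "outer_skull", "inner_skull", "brain"))

  # every inner-skull vertex strictly inside the scalp ellipsoid
  ax <- synth_spec()$scalp_semiaxes
  nr <- sqrt(rowSums(sweep(tmpl$surfaces$inner_skull$vertices, 2, ax, `/`)^2))
  expect_true(all(nr < 1))

  # fiducials lie exactly on the faceted scalp
  fm <- rbind(tmpl$fiducials$nasion, tmpl$fiducials$lpa, tmpl$fiducials$rpa)
  expect_lt(max(point_mesh_distances(fm, tmpl$surfaces$scalp)), 1e-6)

  # volume voxel at the head centroid carries the innermost label
  aseg <- tmpl$volumes$aseg
  ctr_vox <- round(pseudomri:::world_to_voxel(aseg, matrix(0, 1, 3))) + 1
  expect_equal(aseg$data[ctr_vox[1], ctr_vox[2], ctr_vox[3]], 4)

  # determinism: same spec -> identical bundle
  t2 <- make_template(test_spec())
  expect_identical(t2$surfaces$scalp$vertices, tmpl$surfaces$scalp$vertices)
  expect_identical(t2$volumes$T1$data, tmpl$volumes$T1$data)
})

test_that("subject deformation has the stated amplitude and exact ground truth", {
  tmpl <- small_template()
  for (mode in c("affine", "harmonic", "tps")) {
    spec <- test_spec(deform_mode = mode, deform_amplitude_mm = 8, seed = 3)
    subj <- make_subject(tmpl, spec)
    # ground-truth warp reproduces the subject scalp exactly
    gt_scalp <- subj$ground_truth(tmpl$surfaces$scalp$vertices)
    expect_lt(max(abs(gt_scalp - subj$bundle$surfaces$scalp$vertices)), 1e-9)
    if (mode == "harmonic") {
      disp <- max(sqrt(rowSums((gt_scalp - tmpl$surfaces$scalp$vertices)^2)))
      expect_gte(disp, 7); expect_lte(disp, 9)
      # analytic inverse round-trips to machine precision
      back <- subj$ground_truth_inverse(gt_scalp)
      expect_lt(max(abs(back - tmpl$surfaces$scalp$vertices)), 1e-9)
    }
  }
  # amplitude 0 leaves the template unchanged
  sub0 <- make_subject(tmpl, test_spec(deform_mode = "harmonic",
                                       deform_amplitude_mm = 0, seed = 3))
  expect_lt(max(abs(sub0$bundle$surfaces$scalp$vertices -
                      tmpl$surfaces$scalp$vertices)), 1e-9)
  expect_error(make_subject(tmpl, test_spec(deform_mode = "none")),
               class = "invalid_spec")
})

test_that("digitization sampling honors count, plane, mask, noise and standoff", {
  tmpl <- small_template(3L)
  scalp <- tmpl$surfaces$scalp
  fids <- tmpl$fiducials

  dig <- sample_digitization(scalp, fids, test_spec(n_points = 150, seed = 4))
  expect_equal(nrow(dig$points), 150)
  d <- fiducial_plane_distances(fids, dig$points, toward = c(0, 0, 1e6))
  expect_true(all(d > -4))  # above the plane up to standoff+noise slack

  # zero noise and standoff: points on the surface
  clean <- sample_digitization(scalp, fids,
                               test_spec(n_points = 80, noise_std_mm = 0,
                                         standoff_mm = 0, seed = 4))
  expect_lt(max(point_mesh_distances(clean$points, scalp)), 1e-6)

  # noise estimator consistency at large n: STD of signed normal offsets
  big <- sample_digitization(scalp, fids,
                             test_spec(n_points = 5000, seed = 8))
  offsets <- point_mesh_distances(big$points, scalp)
  ax <- synth_spec()$scalp_semiaxes
  inside <- sqrt(rowSums(sweep(big$points, 2, ax, `/`)^2)) < 1
  offsets[inside] <- -offsets[inside]
  expect_equal(sd(offsets), 0.94, tolerance = 0.08)

  # coverage mask excludes the cap and keeps the count
  mask <- list(direction = c(-0.5, 0, 0.85), angle_deg = 40)
  masked <- sample_digitization(scalp, fids,
                                test_spec(n_points = 150, seed = 4,
                                          coverage_mask = mask))
  expect_equal(nrow(masked$points), 150)
  mdir <- mask$direction / sqrt(sum(mask$direction^2))
  dirs <- masked$points / sqrt(rowSums(masked$points^2))
  expect_true(all(dirs %*% mdir < cos(40 * pi / 180) + 0.05))

  # an absurd mask triggers the coverage error
  expect_error(sample_digitization(scalp, fids,
                                   test_spec(n_points = 150, seed = 4,
                                             coverage_mask = list(
                                               direction = c(0, 0, 1),
                                               angle_deg = 175))),
               class = "coverage_error")

  # outliers are displaced by the configured distance
  outs <- sample_digitization(scalp, fids,
                              test_spec(n_points = 100, outlier_frac = 0.1,
                                        outlier_dist_mm = 40, seed = 4))
  far <- sum(point_mesh_distances(outs$points, scalp) > 20)
  expect_equal(far, 10)

  # determinism per seed; a different seed changes the draw
  again <- sample_digitization(scalp, fids, test_spec(n_points = 150, seed = 4))
  expect_identical(again$points,
                   sample_digitization(scalp, fids,
                                       test_spec(n_points = 150, seed = 4))$points)
  other <- sample_digitization(scalp, fids, test_spec(n_points = 150, seed = 5))
  expect_false(identical(again$points, other$points))
})

test_that("clean digitization survives conditioning within the rejection band", {
  tmpl <- small_template(3L)
  dig <- sample_digitization(tmpl$surfaces$scalp, tmpl$fiducials,
                             test_spec(n_points = 150, seed = 12))
  res <- condition_digitization(dig$points, tmpl$fiducials,
                                tmpl$surfaces$scalp, conditioning_config(),
                                seed = 1)
  removed <- res$report$after_plane_filter - res$report$after_outlier_rejection
  expect_lte(removed / res$report$after_plane_filter, 0.10)
})
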