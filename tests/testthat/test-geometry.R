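rigid_to_mat4 <- pseudomri:::rigid_to_mat4

test_that("head frame follows the fiducial convention", {
  # already in head frame -> identity
  fid <- fiducials(c(0, 95, 0), c(-75, 0, 0), c(75, 0, 0))
  tf <- define_head_frame(fid)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(tf$translation)), 1e-12)

  # pure translation is undone
  off <- c(10, -5, 3)
  fid2 <- fiducials(c(0, 95, 0) + off, c(-75, 0, 0) + off, c(75, 0, 0) + off)
  tf2 <- define_head_frame(fid2)
  expect_lt(max(abs(tf2$rotation - diag(3))), 1e-12)
  expect_equal(tf2$translation, -off, tolerance = 1e-12)

  # rotation about z is recovered: T composed with R is identity on fids
  ang <- 30 * pi / 180
  rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  m <- rbind(c(0, 95, 0), c(-75, 0, 0), c(75, 0, 0)) %*% t(rz)
  tf3 <- define_head_frame(fiducials(m[1, ], m[2, ], m[3, ]))
  back <- apply_rigid(tf3, m)
  expect_lt(max(abs(back - rbind(c(0, 95, 0), c(-75, 0, 0), c(75, 0, 0)))), 1e-9)

  # frame placement contract: lpa/rpa on x axis, nasion on +y
  set.seed(11)
  for (i in 1:5) {
    r <- random_rotation(); t0 <- rnorm(3, sd = 40)
    m <- sweep(rbind(c(0, 90, 0), c(-70, 0, 0), c(80, 0, 0)) %*% t(r), 2, -t0)
    h <- apply_rigid(define_head_frame(fiducials(m[1, ], m[2, ], m[3, ])), m)
    expect_lt(max(abs(h[1, c(1, 3)])), 1e-9)   # nasion x=z=0
    expect_gt(h[1, 2], 0)
    expect_lt(max(abs(h[2:3, 2:3])), 1e-9)     # lpa/rpa y=z=0
    expect_true(h[2, 1] < 0 && h[3, 1] > 0)
  }

  expect_error(fiducials(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "invalid_fiducials")
})

test_that("rigid landmark fit recovers exact rigid motions", {
  set.seed(21)
  src <- matrix(rnorm(30, sd = 50), 10, 3)
  expect_lt(max(abs(rigid_to_mat4(fit_rigid_landmarks(src, src)) - diag(4))),
            1e-9)

  tf <- fit_rigid_landmarks(src, sweep(src, 2, -c(5, 5, 5)))
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)
  expect_equal(tf$translation, c(5, 5, 5), tolerance = 1e-9)

  for (i in 1:10) {
    r <- random_rotation(); t0 <- rnorm(3, sd = 30)
    dst <- sweep(src %*% t(r), 2, -t0)
    fit <- fit_rigid_landmarks(src, dst)
    expect_lt(max(abs(fit$rotation - r)), 1e-9)
    expect_lt(max(abs(fit$translation - t0)), 1e-9)
    expect_lt(max(sqrt(rowSums((apply_rigid(fit, src) - dst)^2))), 1e-9)
    # residual invariant to relabeling order of pairs
    perm <- sample(nrow(src))
    fit2 <- fit_rigid_landmarks(src[perm, ], dst[perm, ])
    expect_lt(max(abs(fit2$rotation - fit$rotation)), 1e-9)
  }

  expect_error(fit_rigid_landmarks(src[1:2, ], src[1:2, ]),
               class = "insufficient_landmarks")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_rigid_landmarks(line, line),
               class = "insufficient_landmarks")
})

test_that("point-to-mesh distances match the brute-force oracle", {
  mesh <- unit_sphere_mesh(1, radius = 100)  # 80 faces
  expect_equal(point_mesh_distances(mesh$vertices[5, , drop = FALSE], mesh), 0)
  # point above the interior of one horizontal triangle
  tri <- trimesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)), rbind(1:3))
  expect_equal(point_mesh_distances(matrix(c(2, 2, 7), 1, 3), tri), 7)

  set.seed(31)
  pts <- matrix(rnorm(150, sd = 120), 50, 3)
  expect_equal(point_mesh_distances(pts, mesh), oracle_mesh_dist(pts, mesh),
               tolerance = 1e-9)
  expect_error(point_mesh_distances(pts, trimesh(matrix(0, 0, 3),
                                                 matrix(0L, 0, 3))),
               class = "empty_geometry")
})

test_that("radial projection hits the outermost crossing on the mesh", {
  mesh <- unit_sphere_mesh(2, radius = 100)
  # on-mesh point projects to itself
  v <- mesh$vertices[10, , drop = FALSE]
  expect_lt(max(abs(radial_project(v, mesh)$points - v)), 1e-9)
  # exterior point on the z axis lands at the top of the sphere
  top <- radial_project(matrix(c(0, 0, 250), 1, 3), mesh)$points
  expect_lt(abs(top[3] - 100), 0.7)  # facet sag tolerance
  expect_lt(max(abs(top[1:2])), 1e-9)

  set.seed(32)
  pts <- matrix(rnorm(60, sd = 150), 20, 3)
  pts <- pts[sqrt(rowSums(pts^2)) > 110, , drop = FALSE]
  res <- radial_project(pts, mesh)
  for (i in seq_len(nrow(pts))) {
    d <- pts[i, ] / sqrt(sum(pts[i, ]^2))
    ts <- oracle_ray_hits(c(0, 0, 0), d, mesh)
    expect_gt(length(ts), 0)
    expect_lt(max(abs(res$points[i, ] - max(ts) * d)), 1e-8)
  }
  # projection output always lies on the surface
  expect_lt(max(point_mesh_distances(res$points, mesh)), 1e-6)
})

test_that("farthest-point downsampling keeps spread-out subsets", {
  set.seed(41)
  pts <- matrix(rnorm(360), 120, 3)
  out <- farthest_point_downsample(pts, 300, seed = 1)
  expect_identical(out$points, pts)  # no-op branch

  seg <- rbind(c(-10, 0, 0), c(10, 0, 0), c(0, 0, 0))
  two <- farthest_point_downsample(seg, 2, seed = 1)$points
  expect_true(all(c(-10, 10) %in% two[, 1]))

  cloud <- matrix(rnorm(3000), 1000, 3)
  cloud <- cloud / sqrt(rowSums(cloud^2)) * 100
  fps <- farthest_point_downsample(cloud, 100, seed = 3)
  expect_equal(nrow(fps$points), 100)
  expect_true(all(fps$index %in% seq_len(1000)))
  min_pair <- function(m) min(dist(m))
  fps_min <- min_pair(fps$points)
  for (i in 1:100) {
    sub <- cloud[sample(1000, 100), ]
    expect_gte(fps_min, min_pair(sub))
  }
  # determinism given seed
  fps2 <- farthest_point_downsample(cloud, 100, seed = 3)
  expect_identical(fps$index, fps2$index)
})

test_that("fiducial plane distances are signed toward the head top", {
  fid <- fiducials(c(0, 95, 0), c(-75, 0, 0), c(75, 0, 0))
  pts <- rbind(c(0, 0, 50), c(0, 0, -15), c(10, 20, -5))
  d <- fiducial_plane_distances(fid, pts, toward = c(0, 0, 100))
  expect_equal(d, c(50, -15, -5), tolerance = 1e-12)
  expect_error(fiducial_plane_distances(fid, pts, toward = c(5, 5, 0)),
               class = "orientation_error")
})
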