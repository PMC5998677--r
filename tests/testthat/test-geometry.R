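test_that("angulation construction canonicalizes and validates", {
  a <- angulation(190, -200, 180)
  expect_equal(as.numeric(a), c(-170, 160, 180))
  expect_equal(canonical_angle(-180), 180)
  expect_error(angulation(NaN, 0, 0), "finite")
  expect_error(angulation(Inf, 0, 0), "finite")
})

test_that("rotation_from_angulation follows the Rz Ry Rx convention", {
  expect_equal(rotation_from_angulation(c(0, 0, 0)), diag(3))
  # quarter turn about x carries +y to +z
  R <- rotation_from_angulation(c(90, 0, 0))
  expect_equal(as.numeric(R %*% c(0, 1, 0)), c(0, 0, 1), tolerance = 1e-12)
  # quarter turn about z carries +x to +y
  R <- rotation_from_angulation(c(0, 0, 90))
  expect_equal(as.numeric(R %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  expect_error(rotation_from_angulation(c(NA, 0, 0)), "finite")
})

test_that("angulation round-trips through its rotation matrix", {
  for (ang in list(c(7.0, 20.0, 15.0), c(16.9, 5.8, 25.3),
                   c(15.9, 3.3, -1.7), c(15.8, 1.7, 27.4))) {
    back <- angulation_from_rotation(rotation_from_angulation(ang))
    expect_equal(as.numeric(back), ang, tolerance = 1e-6)
  }
  expect_equal(as.numeric(angulation_from_rotation(diag(3))), c(0, 0, 0))
})

test_that("round trip holds over 10,000 random angulations away from gimbal lock", {
  set.seed(42)
  n <- 10000
  ts <- runif(n, -179, 179)
  tc <- runif(n, -89, 89)
  rt <- runif(n, -179, 179)
  worst <- 0
  for (i in seq_len(n)) {
    a <- c(ts[i], tc[i], rt[i])
    R <- rotation_from_angulation(a)
    b <- as.numeric(angulation_from_rotation(R))
    worst <- max(worst, max(abs(b - a)))
  }
  expect_lt(worst, 1e-6)
})

test_that("constructed rotations are orthonormal with determinant +1", {
  set.seed(7)
  for (i in 1:50) {
    R <- rotation_from_angulation(runif(3, -180, 180))
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("decomposition refuses gimbal lock and bad matrices", {
  expect_error(angulation_from_rotation(rotation_from_angulation(c(10, 90, 5))),
               "gimbal")
  expect_error(angulation_from_rotation(rotation_from_angulation(c(0, -90, 0))),
               "gimbal")
  # row norms != 1
  expect_error(angulation_from_rotation(diag(3) * 1.01), "orthonormal")
  expect_error(angulation_from_rotation(matrix(1, 3, 3)), "orthonormal")
  # reflection (det -1)
  expect_error(angulation_from_rotation(diag(c(1, 1, -1))), "orthonormal")
})

test_that("voxel_spec validates its fields", {
  expect_error(voxel_spec("s", "d", c(10, -1, 10), c(0, 0, 0), c(0, 0, 0)),
               "positive")
  expect_error(voxel_spec("s", "d", c(10, 10, 10), c(0, 0, 0), c(0, 0, 0),
                          orientation = "LAB"), "orientation")
  expect_error(voxel_spec("s", "d", c(10, 10, 10), c(0, 0, 0), c(0, 0, 0),
                          orientation = "LLS"), "orientation")
  s <- voxel_spec("s", "d", c(15, 20, 15), c(1, 2, 3), c(0, 0, 0), "ras")
  expect_equal(s$orientation, "RAS")
  expect_equal(nominal_volume(s), 4500)
  expect_false(is_rotated(s))
  expect_true(is_rotated(voxel_spec("s", "d", c(1, 1, 1), c(0, 0, 0),
                                    c(0, 0.1, 0))))
})

test_that("delta_pose reproduces the extreme-position bookkeeping rows", {
  tmpl <- table1_template_spec()
  a <- voxel_spec("dlpfc_study", "A", c(15, 20, 15), c(23, 20, 35),
                  c(16.9, 5.8, 25.3))
  b <- voxel_spec("dlpfc_study", "B", c(15, 20, 15), c(50, -1.4, 27),
                  c(15.9, 3.3, -1.7))
  cc <- voxel_spec("dlpfc_study", "C", c(15, 20, 15), c(19, 13, 32),
                   c(15.8, 1.7, 27.4))
  da <- delta_pose(tmpl, a)
  expect_equal(da$translation, c(-9, -5, 12.5))
  expect_equal(unname(da$rotation), c(9.9, -14.2, 10.3))
  db <- delta_pose(tmpl, b)
  expect_equal(db$translation, c(18, -26.4, 4.5))
  expect_equal(unname(db$rotation), c(8.9, -16.7, -16.7))
  dc <- delta_pose(tmpl, cc)
  expect_equal(dc$translation, c(-13, -12, 9.5))
  expect_equal(unname(dc$rotation), c(8.8, -18.3, 12.4))
})

test_that("delta_pose is antisymmetric and zero on itself", {
  tmpl <- table1_template_spec()
  a <- voxel_spec("dlpfc_study", "A", c(15, 20, 15), c(23, 20, 35),
                  c(16.9, 5.8, 25.3))
  d1 <- delta_pose(tmpl, a); d2 <- delta_pose(a, tmpl)
  expect_equal(d1$translation, -d2$translation)
  expect_equal(unname(d1$rotation), -unname(d2$rotation))
  d0 <- delta_pose(tmpl, tmpl)
  expect_equal(d0$translation, c(0, 0, 0))
  expect_equal(unname(d0$rotation), c(0, 0, 0))
  ras <- voxel_spec("s", "d", c(1, 1, 1), c(0, 0, 0), c(0, 0, 0), "RAS")
  las <- voxel_spec("s", "d", c(1, 1, 1), c(0, 0, 0), c(0, 0, 0), "LAS")
  expect_error(delta_pose(ras, las), "orientation")
})

test_that("voxel corners preserve edge lengths and centroid", {
  s <- voxel_spec("s", "d", c(2, 2, 2), c(0, 0, 0), c(0, 0, 0))
  cor <- voxel_corners(s)
  expect_equal(sort(unique(abs(as.numeric(cor)))), 1)
  # rotated: centroid equals centre, edges recover the dims
  s2 <- voxel_spec("s", "d", c(15, 20, 15), c(32, 25, 22.5), c(7, 20, 15))
  cor2 <- voxel_corners(s2)
  expect_equal(colMeans(cor2), c(x = 32, y = 25, z = 22.5))
  # corner rows follow expand.grid order over (x, y, z) signs
  edge_pairs <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),   # x edges
                      c(1, 3), c(2, 4), c(5, 7), c(6, 8),   # y edges
                      c(1, 5), c(2, 6), c(3, 7), c(4, 8))   # z edges
  lens <- apply(edge_pairs, 1, function(p)
    sqrt(sum((cor2[p[1], ] - cor2[p[2], ])^2)))
  expect_equal(lens, rep(c(15, 20, 15), each = 4), tolerance = 1e-9)
})

test_that("rigid transforms validate, compose associatively and invert", {
  expect_error(rigid_transform(rotation = diag(3) * 1.001), "orthonormal")
  set.seed(3)
  ts <- lapply(1:3, function(i)
    rigid_transform(rotation_from_angulation(runif(3, -40, 40)),
                    runif(3, -10, 10)))
  ab_c <- tf_compose(tf_compose(ts[[1]], ts[[2]]), ts[[3]])
  a_bc <- tf_compose(ts[[1]], tf_compose(ts[[2]], ts[[3]]))
  expect_equal(ab_c$matrix, a_bc$matrix, tolerance = 1e-12)
  for (t in ts) {
    id <- tf_compose(t, tf_invert(t))
    expect_lt(max(abs(id$matrix - diag(4))), 1e-9)
  }
  expect_s3_class(tf_compose(ts[[1]], ts[[2]]), "rigid_transform")
})

test_that("9-dof transforms decompose as rotation times positive scale", {
  R <- rotation_from_angulation(c(10, -5, 20))
  t9 <- affine_transform9(R, scales = c(1.1, 0.9, 1.05),
                          translation = c(1, 2, 3))
  back <- affine_transform9(matrix = t9$matrix)
  expect_equal(back$scales, c(1.1, 0.9, 1.05), tolerance = 1e-9)
  expect_error(affine_transform9(R, scales = c(1, -1, 1)), "positive")
  # shear-bearing matrix is refused
  m <- diag(4); m[1, 2] <- 0.3
  expect_error(affine_transform9(matrix = m), "orthonormal")
  # applying to points matches direct arithmetic
  p <- c(4, 5, 6)
  expect_equal(tf_apply(t9, p),
               as.numeric(R %*% diag(c(1.1, 0.9, 1.05)) %*% p + c(1, 2, 3)),
               tolerance = 1e-12)
})
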