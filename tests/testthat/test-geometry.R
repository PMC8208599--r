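test_that("projection matrix maps the isocenter to the detector center", {
  g <- micro_geometry()
  for (k in c(1, 7, 16, 31)) {
    h <- projection_matrix(g, k) %*% c(0, 0, 0, 1)
    expect_equal(h[1] / h[3], (g$detector_cols + 1) / 2)
    expect_equal(h[2] / h[3], (g$detector_rows + 1) / 2)
  }
})

test_that("axial displacement magnifies by SDD/SID onto detector rows", {
  g <- micro_geometry()
  d <- 10
  p <- project_points(c(0, 0, d), g, 5)
  expect_equal(unname(p[1, "row"]) - (g$detector_rows + 1) / 2,
               d * g$source_detector_distance /
                 g$source_isocenter_distance / g$pixel_spacing)
  expect_equal(unname(p[1, "col"]), (g$detector_cols + 1) / 2)
})

test_that("projection matrix agrees with brute-force ray/plane intersection", {
  g <- micro_geometry()
  sid <- g$source_isocenter_distance
  sdd <- g$source_detector_distance
  set.seed(11)
  for (i in 1:20) {
    x <- runif(3, -80, 80)
    k <- sample(g$num_views, 1)
    th <- view_angles(g)[k]
    e_s <- c(cos(th), sin(th), 0)
    e_u <- c(-sin(th), cos(th), 0)
    S <- sid * e_s
    D0 <- -(sdd - sid) * e_s
    dirv <- x - S
    t <- sum((D0 - S) * e_s) / sum(dirv * e_s)
    X <- S + t * dirv
    expected <- c(sum((X - D0) * e_u) / g$pixel_spacing +
                    (g$detector_cols + 1) / 2,
                  X[3] / g$pixel_spacing + (g$detector_rows + 1) / 2)
    got <- project_points(x, g, k)
    expect_lt(abs(got[1, "col"] - expected[1]), 1e-9)
    expect_lt(abs(got[1, "row"] - expected[2]), 1e-9)
  }
})

test_that("consecutive views differ by a rotation about the z axis", {
  g <- micro_geometry()
  dth <- g$angular_increment * pi / 180
  Rz <- matrix(c(cos(dth), sin(dth), 0, -sin(dth), cos(dth), 0, 0, 0, 1),
               3, 3)
  set.seed(12)
  pts <- matrix(runif(30, -90, 90), 10)
  for (k in 1:(g$num_views - 1)) {
    a <- project_points(pts %*% t(Rz), g, k + 1)
    b <- project_points(pts, g, k)
    expect_lt(max(abs(a - b)), 1e-6)
  }
})

test_that("geometry and containers validate their inputs", {
  expect_error(cone_beam_geometry(700, 650, 48, 64, 1, 10), "source_detector")
  expect_error(projection_matrix(micro_geometry(), 32), "out of range")
  expect_error(projection_matrix(micro_geometry(), 0), "out of range")
  expect_error(volume_grid(c(0, 4, 4), 1))
  g <- micro_geometry()
  expect_error(projection_stack(array(0, c(2, 2, 2)), g))
  expect_silent(projection_stack(array(0, c(48, 64, 31)), g))
})

test_that("detector offsets shift the principal point", {
  g <- cone_beam_geometry(650, 1198, 48, 64, 6.16, 31,
                          start_angle = 0, angular_increment = 6.4,
                          detector_offset = c(6.16, -12.32))
  h <- projection_matrix(g, 3) %*% c(0, 0, 0, 1)
  expect_equal(h[1] / h[3], (64 + 1) / 2 - 1)  # u offset = +1 px
  expect_equal(h[2] / h[3], (48 + 1) / 2 + 2)  # v offset = -2 px
})
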