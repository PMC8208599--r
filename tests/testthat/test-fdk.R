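test_that("Parker weights of conjugate rays sum to one", {
  G <- 9.2 * pi / 180
  set.seed(31)
  beta <- runif(5000, 0, pi + 2 * G)
  gam <- runif(5000, -G + 1e-6, G - 1e-6)
  bconj <- beta + pi - 2 * gam
  inside <- bconj >= 0 & bconj <= pi + 2 * G
  expect_gt(sum(inside), 100)
  s <- parker_weight(0, 0, G)  # touch once for vectorized path below
  sums <- vapply(which(inside), function(i)
    parker_weight(beta[i], gam[i], G) +
      parker_weight(bconj[i], -gam[i], G), 0)
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("Parker weighting falls back or errors by angular span", {
  full <- cone_beam_geometry(650, 1198, 8, 16, 6.16, 120,
                             angular_increment = 3)
  expect_equal(parker_weights(full), matrix(0.5, 120, 16))
  short <- cone_beam_geometry(650, 1198, 8, 16, 6.16, 10,
                              angular_increment = 10)
  expect_error(parker_weights(short), "span")
})

test_that("a uniform cylinder reconstructs to its true attenuation", {
  g <- fx_preset()$geometry
  ph <- analytic_phantom(list(list(
    shape = "cylinder", center = c(0, 0, 0), material = "water",
    priority = 1, radii = c(50, 50), half_length = 170)))
  sc <- simulate_scan(ph, g, mono_spectrum(60), supersample = 1)
  grid <- volume_grid(c(96, 96, 96), c(2.2, 2.2, 1.4))
  vol <- fdk_reconstruct(sc$stack, g, grid)
  mu <- material_attenuation("water", 60)
  ctr <- voxel_centers(grid)
  inner <- array(sqrt(ctr[, 1]^2 + ctr[, 2]^2) < 25, grid$size) &
    array(abs(ctr[, 3]) < 40, grid$size)
  expect_lt(abs(mean(vol[inner]) / mu - 1), 0.03)
  expect_lt(sd(vol[inner]) / mean(vol[inner]), 0.02)
})

test_that("FDK of a zero stack is zero", {
  g <- micro_geometry()
  vol <- fdk_reconstruct(array(0, c(48, 64, 31)), g, micro_grid())
  expect_true(all(vol == 0))
})

test_that("simulator line integrals match the ray-driven projector", {
  # monochromatic single-material limit: analytic intersections vs
  # trilinear ray marching through a voxelized indicator
  g <- micro_geometry()
  grid <- volume_grid(c(96, 96, 64), c(2.2, 2.2, 2.8))
  mu <- material_attenuation("water", 60)
  ph <- analytic_phantom(list(list(
    shape = "ellipsoid", center = c(10, -5, 0), material = "water",
    priority = 1, semi = c(60, 45, 50))))
  sc <- simulate_scan(ph, g, mono_spectrum(60), supersample = 1)
  ctr <- voxel_centers(grid)
  inside <- ((ctr[, 1] - 10) / 60)^2 + ((ctr[, 2] + 5) / 45)^2 +
    (ctr[, 3] / 50)^2 <= 1
  fp <- forward_project(array(mu * inside, grid$size), grid, g)
  li <- sc$stack$data
  sel <- li > 0.5   # rays well inside the ellipsoid
  relerr <- abs(fp[sel] - li[sel]) / li[sel]
  expect_lt(median(relerr), 0.01)
  expect_lt(mean(relerr), 0.02)
})
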