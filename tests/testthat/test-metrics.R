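# naive SSIM oracle: explicit double loop over window positions
ssim_naive <- function(a, b, data_range, sigma = 1.5, radius = 5) {
  k1d <- exp(-(-radius:radius)^2 / (2 * sigma^2))
  K <- outer(k1d, k1d)
  K <- K / sum(K)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  vals <- c()
  for (r in (radius + 1):(nrow(a) - radius)) {
    for (c in (radius + 1):(ncol(a) - radius)) {
      wa <- a[(r - radius):(r + radius), (c - radius):(c + radius)]
      wb <- b[(r - radius):(r + radius), (c - radius):(c + radius)]
      mu1 <- sum(K * wa); mu2 <- sum(K * wb)
      v1 <- sum(K * wa^2) - mu1^2
      v2 <- sum(K * wb^2) - mu2^2
      cv <- sum(K * wa * wb) - mu1 * mu2
      vals <- c(vals, (2 * mu1 * mu2 + C1) * (2 * cv + C2) /
                  ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2)))
    }
  }
  mean(vals)
}

test_that("identical volumes have SSIM one and nRMSE zero", {
  set.seed(81)
  v <- array(runif(20^3), c(20, 20, 20))
  expect_equal(ssim_volume(v, v), 1)
  expect_equal(nrmse_volume(v, v), 0)
})

test_that("anti-correlated volumes have negative SSIM", {
  # a zero-local-mean pattern isolates the covariance term: with matched
  # (vanishing) local means, sign-flipping the volume flips the structure
  # term and the score goes negative
  g <- expand.grid(x = 1:24, y = 1:24, z = 1:8)
  v <- array(sin(2 * pi * g$x / 4) * sin(2 * pi * g$y / 4) *
               (1 + 0.2 * sin(g$z)), c(24, 24, 8))
  expect_lt(ssim_volume(-v, v, data_range = 2), 0)
})

test_that("SSIM matches a naive windowed implementation to 1e-6", {
  set.seed(83)
  a <- matrix(runif(24 * 30), 24, 30)
  b <- a + matrix(rnorm(24 * 30, 0, 0.1), 24, 30)
  rng <- max(a) - min(a)
  expect_lt(abs(ssim_volume(array(a, c(24, 30, 1)),
                            array(b, c(24, 30, 1)), data_range = rng) -
                  ssim_naive(a, b, rng)), 1e-6)
})

test_that("a constant offset has the closed-form nRMSE", {
  set.seed(84)
  ref <- array(runif(15^3, 0, 2), c(15, 15, 15))
  rng <- max(ref) - min(ref)
  for (cc in c(0.05, 0.3)) {
    expect_equal(nrmse_volume(ref + cc * rng, ref), cc)
  }
  v <- array(rnorm(15^3), c(15, 15, 15))
  expect_equal(nrmse_volume(v, ref),
               sqrt(mean((v - ref)^2)) / rng)
})

test_that("metric preconditions are enforced", {
  v <- array(0, c(5, 5, 5))
  expect_error(nrmse_volume(v, v), "zero value range")
  expect_error(ssim_volume(v, array(0, c(6, 5, 5))))
  expect_error(ssim_volume(v, v), "data_range")
  expect_error(strip_boundary(array(0, c(4, 10, 10)), 2))
})

test_that("the 3D window option agrees closely with slice averaging", {
  set.seed(85)
  a <- array(runif(20^3), c(20, 20, 20))
  b <- a + array(rnorm(20^3, 0, 0.05), c(20, 20, 20))
  s2 <- ssim_volume(a, b, window = "slice")
  s3 <- ssim_volume(a, b, window = "3d")
  expect_lt(abs(s2 - s3), 0.05)
})
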