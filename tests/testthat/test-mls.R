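# brute-force oracle: solve the weighted affine least squares
#   min sum_i w_i |A p_i + b - q_i|^2
# directly via normal equations on the 12 unknowns
mls_oracle <- function(v, p, q, alpha = 1) {
  w <- 1 / rowSums(sweep(p, 2, v)^2)^alpha
  X <- cbind(p, 1)
  XtW <- t(X * w)
  M <- solve(XtW %*% X, XtW %*% q)   # 4 x 3: rows = A columns and b
  as.numeric(c(v, 1) %*% M)
}

test_that("identical control points give the identity map", {
  set.seed(61)
  p <- matrix(runif(33, -50, 50), 11)
  def <- mls_deformation(p, p)
  v <- matrix(runif(60, -80, 80), 20)
  expect_equal(mls_transform(v, def), v, tolerance = 1e-9)
})

test_that("a pure translation is reproduced exactly everywhere", {
  set.seed(62)
  p <- matrix(runif(33, -50, 50), 11)
  d <- c(7, -3, 12)
  def <- mls_deformation(p, p + rep(d, each = 11))
  v <- matrix(runif(60, -200, 200), 20)
  expect_equal(mls_transform(v, def), v + rep(d, each = 20),
               tolerance = 1e-9)
})

test_that("control points are interpolated exactly", {
  set.seed(63)
  p <- matrix(runif(33, -50, 50), 11)
  q <- p + matrix(rnorm(33, 0, 5), 11)
  def <- mls_deformation(p, q)
  expect_equal(mls_transform(p[3, ], def), q[3, ])
  expect_equal(mls_transform(p, def), q, tolerance = 1e-9)
})

test_that("the affine solve matches the brute-force oracle to 1e-9 mm", {
  set.seed(64)
  for (alpha in c(0.5, 1, 2)) {
    p <- matrix(runif(33, -60, 60), 11)
    q <- p + matrix(rnorm(33, 0, 8), 11)
    def <- mls_deformation(p, q, alpha = alpha)
    expect_identical(def$solve_mode, "affine")
    for (i in 1:8) {
      v <- runif(3, -100, 100)
      expect_lt(max(abs(mls_transform(v, def) -
                          mls_oracle(v, p, q, alpha))), 1e-9)
    }
  }
})

test_that("coplanar controls warn and fall back to a rigid solve", {
  set.seed(65)
  p <- cbind(runif(8, -50, 50), runif(8, -50, 50), 0)  # exactly coplanar
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  q <- p %*% t(R) + rep(c(5, -2, 3), each = 8)
  expect_warning(def <- mls_deformation(p, q), "coplanar")
  expect_identical(def$solve_mode, "rigid")
  # the rigid motion is recovered exactly, including off-plane points
  v <- matrix(runif(30, -80, 80), 10)
  expect_equal(mls_transform(v, def),
               v %*% t(R) + rep(c(5, -2, 3), each = 10), tolerance = 1e-6)
})

test_that("fewer than four control points are rejected", {
  p <- matrix(runif(9), 3)
  expect_error(mls_deformation(p, p), "4 control points")
})
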