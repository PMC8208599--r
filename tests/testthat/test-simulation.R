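test_that("rays through air carry zero line integral up to quantization", {
  tr <- fx_triple()
  ref <- tr$reference
  k <- 1   # lateral view with plenty of background
  bg <- which(ref$intensity[, , k] > 0.999 * ref$spectrum$I0)
  expect_gt(length(bg), 100)
  # one quantization bin in intensity ~ bin_width / I0 in line integral
  tol <- tr$saturation$bin_width / ref$spectrum$I0 * 1.01
  expect_lt(max(ref$stack$data[, , k][bg]), tol)
})

test_that("clipped pixels follow the overexposure rule", {
  tr <- fx_triple()
  over <- tr$overexposed
  sat <- tr$saturation
  expect_true(any(over$clipped))
  # all clipped pixels had raw intensity above I_max ...
  expect_true(all(over$intensity[over$clipped] > sat$I_max))
  # ... and store the line integral of the clipped, quantized intensity
  imax_q <- floor(sat$I_max / sat$bin_width) * sat$bin_width
  stored <- unique(over$stack$data[over$clipped])
  expect_equal(stored, -log(imax_q / over$spectrum$I0))
})

test_that("clipping lowers intensities and raises stored line integrals", {
  tr <- fx_triple()
  over <- tr$overexposed
  ref <- tr$reference   # same spectrum, clipping skipped
  expect_true(all(pmin(over$intensity, tr$saturation$I_max) <=
                    ref$intensity + 1e-9))
  expect_true(all(over$stack$data >= ref$stack$data - 1e-12))
})

test_that("quantization error is bounded by one bin", {
  tr <- fx_triple()
  ref <- tr$reference
  sat <- tr$saturation
  stored_I <- ref$spectrum$I0 * exp(-ref$stack$data)
  err <- ref$intensity - stored_I
  ok <- !ref$starved
  expect_true(all(err[ok] >= -1e-6 * sat$bin_width))
  expect_true(all(err[ok] < sat$bin_width * (1 + 1e-6)))
})

test_that("lateral low-dose views starve behind the femurs", {
  tr <- fx_triple()
  starved <- tr$lowdose$starved
  lateral <- c(1, 2, 61, 62)
  expect_true(all(vapply(lateral, function(k) any(starved[, , k]), TRUE)))
  # starved pixels are floored to one quantization bin
  floor_li <- -log(tr$saturation$bin_width / tr$lowdose$spectrum$I0)
  expect_equal(unique(tr$lowdose$stack$data[starved]), floor_li)
})

test_that("motion transforms compose as a rigid group", {
  ph <- knee_phantom()
  expect_equal(apply_motion(ph)$markers, ph$markers)
  d <- c(4, -3, 2)
  moved <- apply_motion(ph, left = rigid_motion(d), right = rigid_motion(d))
  expect_equal(moved$markers, ph$markers + rep(d, each = 11))
  back <- apply_motion(apply_motion(ph, left = rigid_motion(rotation_deg = 7)),
                       left = rigid_motion(rotation_deg = -7))
  expect_lt(max(abs(back$markers - ph$markers)), 1e-9)
  expect_error(apply_motion(ph, left = rigid_motion(c(400, 0, 0))),
               "field of view")
})

test_that("the scan triple shares one saturation model", {
  tr <- fx_triple()
  expect_identical(tr$reference$saturation, tr$saturation)
  expect_false(tr$reference$clip)
  expect_true(tr$overexposed$clip)
  # low-dose never clips: I0_low is below I_max by construction
  expect_false(any(tr$lowdose$clipped))
})
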