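test_that("anchor factors are the AEC to low-dose ratio", {
  aec <- c(1, 1, 2.0, 0.5, 0.5, 2.0, 1, 1)
  low <- c(1, 1, 2.5, 1.0, 1.0, 2.5, 1, 1)
  mask <- c(1, 1, 1, 0, 0, 1, 1, 1)
  r <- rowwise_scale(aec, low, mask)
  expect_equal(unique(r$factor[4:5]), 0.8)   # 2.0 / 2.5 on both sides
  expect_equal(r$scaled[4:5], c(0.8, 0.8))
  expect_false(r$flagged)
})

test_that("identical rows scale by one", {
  row <- c(3, 2, 1, 0.5, 0.2, 0.5, 1, 2, 3)
  mask <- c(1, 1, 1, 0, 0, 0, 1, 1, 1)
  r <- rowwise_scale(row, row, mask)
  expect_equal(r$scaled, row)
  expect_equal(unique(na.omit(r$factor)), 1)
})

test_that("starved anchors fall back to the other border and flag", {
  aec <- c(2.0, 0.5, 0.5, 1.8)
  low <- c(0.01, 1.0, 1.0, 2.0)   # left anchor starved
  mask <- c(1, 0, 0, 1)
  r <- rowwise_scale(aec, low, mask)
  expect_true(r$flagged)
  expect_equal(unique(r$factor[2:3]), 1.8 / 2.0)
})

test_that("the seam is exact at every anchor pixel on simulated rows", {
  tr <- fx_triple()
  masks <- fx_masks()
  worst <- 0
  for (k in c(1, 5, 10, 18)) {
    aec <- tr$overexposed$stack$data[, , k]
    low <- tr$lowdose$stack$data[, , k]
    m <- masks$aec_mask[, , k]
    for (r in seq(10, 110, 20)) {
      rs <- rowwise_scale(aec[r, ], low[r, ], m[r, ])
      anchors <- which(!is.na(rs$factor) & m[r, ] == 1)
      if (!length(anchors)) next
      worst <- max(worst, abs(low[r, anchors] * rs$factor[anchors] -
                                aec[r, anchors]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("views with an all-ones mask pass through bit-identically", {
  tr <- fx_triple()
  masks <- fx_masks()
  forced <- masks
  forced$aec_mask[, , 3] <- 1L
  forced$lowdose_mask[, , 3] <- 0L
  out <- combine_projections(tr$overexposed$stack, tr$lowdose$stack, forced)
  expect_identical(out[, , 3], tr$overexposed$stack$data[, , 3])
})

test_that("views outside the lateral correction set are untouched", {
  tr <- fx_triple()
  masks <- fx_masks()
  out <- combine_projections(tr$overexposed$stack, tr$lowdose$stack, masks)
  middle <- setdiff(seq_len(62), masks$correction_views)
  expect_identical(out[, , middle], tr$overexposed$stack$data[, , middle])
})

test_that("combining a stack with itself is the identity", {
  tr <- fx_triple()
  masks <- fx_masks()
  out <- combine_projections(tr$overexposed$stack, tr$overexposed$stack,
                             masks)
  expect_equal(out, tr$overexposed$stack$data, tolerance = 1e-12)
})

test_that("combined views match the reference on valid AEC pixels", {
  tr <- fx_triple()
  fx <- fx_nomotion()
  masks <- fx_masks()
  for (k in masks$correction_views) {
    fg <- masks$aec_mask[, , k] == 1
    same <- fx$combined[, , k][fg] == tr$reference$stack$data[, , k][fg]
    expect_gte(mean(same), 0.99)
  }
})
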