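test_that("backward-forward projection preserves central line integrals", {
  # motion-free: identical marker sets give an identity deformation, so
  # the registered stack is the plain reconstruct-then-reproject of the
  # low-dose scan; in the central region (away from cone/truncation
  # effects) the line integrals survive within a few percent
  p <- fx_preset()
  tr <- fx_triple()
  m <- localize_markers_3d(tr$lowdose$stack, grid = p$grid)
  reg <- register_lowdose_scan(tr$lowdose$stack, m, m, grid = p$grid)
  expect_identical(reg$deformation$p, reg$deformation$q)
  low <- tr$lowdose$stack$data
  syn <- reg$stack$data
  rel <- c()
  # anterior-posterior-ish views: the object is fully inside the lateral
  # field of view there, so no truncated material is missing from the
  # reprojection (lateral views lose the laterally truncated leg parts by
  # construction; the combination re-anchors those rows at the seam)
  for (k in 26:36) {
    sel <- matrix(FALSE, 120, 160)
    sel[45:75, 40:120] <- TRUE              # central detector region
    sel <- sel & low[, , k] > 1 & low[, , k] < 6 & !tr$lowdose$starved[, , k]
    rel <- c(rel, abs(syn[, , k][sel] - low[, , k][sel]) / low[, , k][sel])
  }
  expect_lt(median(rel), 0.05)
})

test_that("registration recovers the inter-scan motion at the markers", {
  fx <- fx_motion()
  p <- fx_preset()
  mapped <- mls_transform(fx$phantom_low$markers, fx$registration$deformation)
  resid <- sqrt(rowSums((mapped - p$phantom$markers)^2))
  expect_lt(mean(resid), 0.5 * max(p$grid$spacing))
})

test_that("registered projections overlap the AEC silhouette better", {
  fx <- fx_motion()
  views <- c(1, 5, 10, 15, 20, 43, 50, 58)
  ref <- fx$triple$reference$stack
  before <- silhouette_overlap(ref, fx$triple$lowdose$stack, views)
  after <- silhouette_overlap(ref, fx$registration$stack, views)
  expect_gt(after, before)
})

test_that("per-view gains are positive and bounded", {
  fx <- fx_motion()
  expect_true(all(fx$registration$gains > 0.5 &
                    fx$registration$gains < 2.5))
})

test_that("marker count mismatch between the scans is an error", {
  fx <- fx_motion()
  expect_error(
    register_lowdose_scan(fx$triple$lowdose$stack,
                          fx$aec_markers$positions[1:9, ],
                          fx$ld_markers, grid = fx_preset()$grid),
    "count mismatch")
})
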