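test_that("all 11 markers are localized within one voxel", {
  p <- fx_preset()
  m <- localize_markers_3d(fx_triple()$overexposed$stack, grid = p$grid)
  expect_equal(nrow(m$positions), 11)
  errs <- marker_errors(m, p$phantom$markers)
  expect_lt(max(errs), max(p$grid$spacing))
  # every ground-truth marker matched (bijectively close)
  expect_equal(length(unique(apply(
    outer(rowSums(m$positions^2), rowSums(p$phantom$markers^2), `+`) -
      2 * m$positions %*% t(p$phantom$markers), 1, which.min))), 11)
})

test_that("localization is equivariant under rigid phantom motion", {
  fx <- fx_motion()
  p <- fx_preset()
  errs <- marker_errors(fx$ld_markers, fx$phantom_low$markers)
  expect_lt(max(errs), max(p$grid$spacing))
})

test_that("a markerless phantom raises a marker-count error", {
  p <- scan_preset("desk", include_markers = FALSE)
  tr <- fx_triple()
  sc <- simulate_scan(p$phantom, p$geometry,
                      tr$overexposed$spectrum,
                      saturation = tr$saturation, clip = TRUE)
  expect_error(localize_markers_3d(sc$stack, p$geometry, p$grid),
               "of 11 markers found")
})

test_that("marker correspondence recovers a known permutation", {
  fx <- fx_motion()
  A <- fx$aec_markers$positions
  B <- fx$ld_markers$positions
  perm <- match_markers(A, B)
  # validate against ground truth: A[i] and B[perm[i]] must be the same
  # physical marker
  p <- fx_preset()
  idA <- apply(outer(rowSums(A^2), rowSums(p$phantom$markers^2), `+`) -
                 2 * A %*% t(p$phantom$markers), 1, which.min)
  idB <- apply(outer(rowSums(B^2), rowSums(fx$phantom_low$markers^2), `+`) -
                 2 * B %*% t(fx$phantom_low$markers), 1, which.min)
  expect_equal(idB[perm], idA)
  expect_error(match_markers(A, B[1:7, ]), "count mismatch")
})

test_that("inpainting fills a disk on constant background exactly", {
  img <- matrix(4.2, 30, 30)
  img[14:16, 14:16] <- 9
  out <- inpaint_markers(array(img, c(30, 30, 1)),
                         list(cbind(15, 15)), radius = 4)
  expect_lt(max(abs(out - 4.2)), 1e-6)
})

test_that("inpainting with no markers is the identity", {
  set.seed(71)
  arr <- array(rnorm(30 * 30 * 2), c(30, 30, 2))
  out <- inpaint_markers(arr, list(matrix(0, 0, 2), matrix(0, 0, 2)),
                         radius = 3)
  expect_identical(out, arr)
  expect_error(inpaint_markers(arr, list(cbind(5, 5), cbind(5, 5)), 0),
               "radius")
})

test_that("pixels outside the inpainted disks are untouched", {
  set.seed(72)
  arr <- array(rnorm(40 * 40 * 1), c(40, 40, 1))
  out <- inpaint_markers(arr, list(cbind(20, 20)), radius = 3)
  changed <- which(out != arr, arr.ind = TRUE)
  d <- sqrt((changed[, 1] - 20)^2 + (changed[, 2] - 20)^2)
  expect_lte(max(d), 3)
})

test_that("inpainting suppresses marker artifacts in the reconstruction", {
  p <- fx_preset()
  tr <- fx_triple()
  # reconstruction of the scan with markers, with and without inpainting,
  # against a markerless phantom reconstruction
  pm <- scan_preset("desk", include_markers = FALSE)
  sc_clean <- simulate_scan(pm$phantom, p$geometry,
                            tr$reference$spectrum,
                            saturation = tr$saturation, clip = FALSE)
  cleaned <- inpaint_markers(tr$reference$stack$data, p$phantom$markers,
                             radius = 2, geometry = p$geometry)
  vol_clean <- fdk_reconstruct(sc_clean$stack, p$geometry, p$grid)
  vol_marked <- fdk_reconstruct(tr$reference$stack, p$geometry, p$grid)
  vol_inpainted <- fdk_reconstruct(cleaned, p$geometry, p$grid)
  # voxels at the marker positions
  idx <- round(sweep(p$phantom$markers, 2, p$grid$origin) %*%
                 diag(1 / p$grid$spacing)) + 1
  sel <- cbind(idx[, 1], idx[, 2], idx[, 3])
  err_marked <- max(abs(vol_marked[sel] - vol_clean[sel]))
  err_inpainted <- max(abs(vol_inpainted[sel] - vol_clean[sel]))
  expect_lt(err_inpainted * 5, err_marked)
})
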