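# Shared fixtures, computed lazily and cached for the whole test run.
# Expensive desk-scale simulations and reconstructions are built once and
# reused across test files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small geometry/grid for cheap operator tests
micro_geometry <- function() {
  cone_beam_geometry(650, 1198, 48, 64, 6.16, 31,
                     start_angle = 90 - 31 * 6.4 / 2,
                     angular_increment = 6.4)
}

micro_grid <- function() volume_grid(c(48, 48, 32), c(4.4, 4.4, 2.8))

# single-energy spectrum for analytic (monochromatic) simulations
mono_spectrum <- function(energy = 60, I0 = 1) {
  structure(list(energies = energy, weights = I0, kvp = energy, mas = 1,
                 I0 = I0),
            class = "xray_spectrum")
}

# canonical inter-scan motions of the experiments
mild_motion <- function() {
  list(left = rigid_motion(c(6, 4, 2), 5),
       right = rigid_motion(c(-5, 6, -2), -4))
}

fx_preset <- function() fixture("preset", function() scan_preset("desk"))

# motion-free desk-scale scan triple
fx_triple <- function() fixture("triple", function() {
  simulate_scan_triple(fx_preset())
})

fx_masks <- function() fixture("masks", function() {
  mask_stack(fx_triple()$overexposed$stack)
})

# motion-free end-to-end: combined stack, three reconstructions, metrics
fx_nomotion <- function() fixture("nomotion", function() {
  p <- fx_preset()
  tr <- fx_triple()
  masks <- fx_masks()
  combined <- combine_projections(tr$overexposed$stack, tr$lowdose$stack,
                                  masks)
  vols <- list(
    overexposed = fdk_reconstruct(tr$overexposed$stack, p$geometry, p$grid),
    corrected = fdk_reconstruct(combined, p$geometry, p$grid),
    reference = fdk_reconstruct(tr$reference$stack, p$geometry, p$grid))
  ref <- strip_boundary(vols$reference)
  metrics <- list(
    ssim_overexposed = ssim_volume(strip_boundary(vols$overexposed), ref),
    nrmse_overexposed = nrmse_volume(strip_boundary(vols$overexposed), ref),
    ssim_corrected = ssim_volume(strip_boundary(vols$corrected), ref),
    nrmse_corrected = nrmse_volume(strip_boundary(vols$corrected), ref))
  list(combined = combined, volumes = vols, metrics = metrics)
})

# mild-motion experiment: localization, registration, combination with and
# without registration, reconstructions, metrics
fx_motion <- function() fixture("motion", function() {
  p <- fx_preset()
  mot <- mild_motion()
  phantom_low <- apply_motion(p$phantom, left = mot$left,
                              right = mot$right)
  tr <- simulate_scan_triple(p, phantom_low = phantom_low)
  aec_markers <- localize_markers_3d(tr$overexposed$stack, grid = p$grid)
  ld_markers <- localize_markers_3d(tr$lowdose$stack, grid = p$grid)
  reg <- register_lowdose_scan(tr$lowdose$stack, aec_markers, ld_markers,
                               grid = p$grid)
  masks <- mask_stack(tr$overexposed$stack)
  comb_reg <- combine_projections(tr$overexposed$stack, reg$stack, masks)
  comb_raw <- combine_projections(tr$overexposed$stack, tr$lowdose$stack,
                                  masks)
  ref_vol <- fdk_reconstruct(tr$reference$stack, p$geometry, p$grid)
  vol_reg <- fdk_reconstruct(comb_reg, p$geometry, p$grid)
  vol_raw <- fdk_reconstruct(comb_raw, p$geometry, p$grid)
  ref <- strip_boundary(ref_vol)
  list(phantom_low = phantom_low, triple = tr,
       aec_markers = aec_markers, ld_markers = ld_markers,
       registration = reg, masks = masks,
       ssim_registered = ssim_volume(strip_boundary(vol_reg), ref),
       ssim_unregistered = ssim_volume(strip_boundary(vol_raw), ref),
       nrmse_registered = nrmse_volume(strip_boundary(vol_reg), ref),
       nrmse_unregistered = nrmse_volume(strip_boundary(vol_raw), ref))
})

# nearest-neighbor distances from estimated marker positions to truth
marker_errors <- function(est, truth) {
  pos <- if (inherits(est, "marker_set")) est$positions else est
  d2 <- outer(rowSums(pos^2), rowSums(truth^2), `+`) - 2 * pos %*% t(truth)
  sqrt(apply(d2, 1, min))
}

# fraction of silhouette agreement between two stacks over given views
silhouette_overlap <- function(stack_a, stack_b, views, threshold = 0.2) {
  a <- stack_data(stack_a)
  b <- stack_data(stack_b)
  mean(vapply(views, function(k) {
    sa <- a[, , k] > threshold
    sb <- b[, , k] > threshold
    sum(sa & sb) / sum(sa | sb)
  }, 0))
}
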