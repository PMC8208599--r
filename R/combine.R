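#' Row-wise scaling of a masked low-dose row at the mask border
#'
#' The AEC and low-dose scans are acquired at different tube voltages, so
#' their line-integral values differ in scale; pasting low-dose pixels into
#' the saturated segments of an AEC row would leave a visible jump at the
#' mask border.  For every zero-segment of the AEC mask in a row, a scale
#' factor is therefore anchored at the adjacent foreground pixels:
#' \code{factor = aec[anchor] / lowdose[anchor]}.  Segments touching
#' foreground on both sides interpolate the two anchor factors linearly
#' across the segment (so the scaled row meets the AEC value exactly at
#' both seams); segments with a single anchor use that factor throughout;
#' segments with no anchor in their row (fully saturated row) fall back to
#' \code{fallback} (the enclosing stack operation passes the nearest row's
#' factor).  Anchors where the low-dose value is at or below
#' \code{starve_floor} (photon-starved or otherwise unusable) are dropped
#' and flagged, as are anchors yielding a factor outside
#' \code{factor_range} (a physically implausible ratio of the two scans'
#' value scales, e.g. from a defective synthesized pixel).
#'
#' @param aec_row,lowdose_row Numeric vectors (one detector row).
#' @param mask_row Binary AEC mask of the row (1 = valid AEC pixel).
#' @param fallback Factor used for segments without any usable anchor
#'   (default 1).
#' @param starve_floor Low-dose values at or below this are unusable as
#'   anchors (default 0.05 line-integral units).
#' @param factor_range Admissible anchor factor interval (default
#'   \code{c(0.2, 5)}).
#' @return List with \code{scaled} (the scaled low-dose row),
#'   \code{factor} (per-pixel factors; anchor pixels carry their anchor
#'   factor, other foreground pixels NA),
#'   \code{mean_factor} (mean anchor factor of the row, NA when the row has
#'   no anchored segment) and \code{flagged} (TRUE when a starved anchor
#'   was dropped).
#' @export
rowwise_scale <- function(aec_row, lowdose_row, mask_row, fallback = 1,
                          starve_floor = 0.05, factor_range = c(0.2, 5)) {
  n <- length(aec_row)
  stopifnot(length(lowdose_row) == n, length(mask_row) == n)
  factor <- rep(NA_real_, n)
  scaled <- lowdose_row
  flagged <- FALSE
  anchor_factors <- numeric(0)
  rl <- rle(as.integer(mask_row) == 0L)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  for (s in which(rl$values)) {
    i0 <- starts[s]; i1 <- ends[s]
    usable <- function(i) {
      if (lowdose_row[i] <= starve_floor) return(NA_real_)
      f <- aec_row[i] / lowdose_row[i]
      if (f < factor_range[1] || f > factor_range[2]) return(NA_real_)
      f
    }
    f_left <- f_right <- NA_real_
    if (i0 > 1) {
      f_left <- usable(i0 - 1)
      if (is.na(f_left)) flagged <- TRUE
    }
    if (i1 < n) {
      f_right <- usable(i1 + 1)
      if (is.na(f_right)) flagged <- TRUE
    }
    if (is.na(f_left) && is.na(f_right)) {
      f <- rep(fallback, i1 - i0 + 1)
    } else if (is.na(f_left)) {
      f <- rep(f_right, i1 - i0 + 1)
      anchor_factors <- c(anchor_factors, f_right)
      factor[i1 + 1] <- f_right
    } else if (is.na(f_right)) {
      f <- rep(f_left, i1 - i0 + 1)
      anchor_factors <- c(anchor_factors, f_left)
      factor[i0 - 1] <- f_left
    } else {
      # linear blend from the left anchor to the right anchor, parameterized
      # over anchor-to-anchor distance so the seam is exact on both sides
      tt <- (seq(i0, i1) - (i0 - 1)) / (i1 + 1 - (i0 - 1))
      f <- (1 - tt) * f_left + tt * f_right
      anchor_factors <- c(anchor_factors, f_left, f_right)
      factor[i0 - 1] <- f_left
      factor[i1 + 1] <- f_right
    }
    factor[i0:i1] <- f
    scaled[i0:i1] <- lowdose_row[i0:i1] * f
  }
  list(scaled = scaled, factor = factor,
       mean_factor = if (length(anchor_factors)) mean(anchor_factors)
                     else NA_real_,
       flagged = flagged)
}

# scale a whole low-dose view against an AEC view and its mask;
# rows without any anchored segment inherit the nearest anchored row's
# mean factor (else 1)
scale_lowdose_view <- function(aec_img, lowdose_img, mask_img,
                               starve_floor = 0.05) {
  nr <- nrow(aec_img)
  res <- vector("list", nr)
  mean_factor <- rep(NA_real_, nr)
  for (r in seq_len(nr)) {
    res[[r]] <- rowwise_scale(aec_img[r, ], lowdose_img[r, ], mask_img[r, ],
                              starve_floor = starve_floor)
    mean_factor[r] <- res[[r]]$mean_factor
  }
  scaled <- lowdose_img
  anchored <- which(!is.na(mean_factor))
  for (r in seq_len(nr)) {
    if (is.na(mean_factor[r]) && any(mask_img[r, ] == 0)) {
      fb <- if (length(anchored))
        mean_factor[anchored[which.min(abs(anchored - r))]] else 1
      res[[r]] <- rowwise_scale(aec_img[r, ], lowdose_img[r, ],
                                mask_img[r, ], fallback = fb,
                                starve_floor = starve_floor)
    }
    scaled[r, ] <- res[[r]]$scaled
  }
  scaled
}

#' Combine AEC and low-dose projections on the lateral view range
#'
#' For each view in \code{correction_views}, the saturated/background
#' pixels of the AEC projection (AEC mask 0) are replaced by the row-wise
#' scaled low-dose pixels; valid AEC pixels are kept unchanged:
#' \code{combined = aec * aec_mask + scale(lowdose) * lowdose_mask}.
#' All other views are returned bit-identically equal to the AEC input,
#' since overexposure only occurs along the lateral direction.  With
#' inter-scan motion the low-dose stack should be the registered stack from
#' [register_lowdose_scan()]; without motion the original projections are
#' used directly.
#'
#' @param aec,lowdose [projection_stack()]s or arrays of equal shape.
#' @param masks A [mask_stack()] of the AEC scan.
#' @param correction_views View indices to combine (default: the mask
#'   stack's correction set).
#' @param starve_floor Passed to [rowwise_scale()].
#' @return Combined projection array (same shape as the inputs).
#' @export
combine_projections <- function(aec, lowdose, masks,
                                correction_views = masks$correction_views,
                                starve_floor = 0.05) {
  a <- stack_data(aec)
  l <- stack_data(lowdose)
  stopifnot(identical(dim(a), dim(l)),
            identical(dim(a), dim(masks$aec_mask)))
  out <- a
  for (k in correction_views) {
    if (!masks$applied[k]) next
    m <- masks$aec_mask[, , k]
    scaled <- scale_lowdose_view(a[, , k], l[, , k], m, starve_floor)
    out[, , k] <- a[, , k] * m + scaled * (1 - m)
  }
  out
}
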