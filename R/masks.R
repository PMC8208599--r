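#' Histogram-based background/saturation threshold of one projection
#'
#' In a saturated (AEC) line-integral projection, background pixels and
#' overexposed pixels share approximately the same (low) value, forming a
#' bell-shaped peak at the low end of the histogram.  The threshold
#' separating them from properly imaged pixels is found as follows:
#' \enumerate{
#'   \item histogram with a fixed bin width of 0.02 (so the number of bins
#'     depends on the image's value range);
#'   \item restrict to the lowest quarter of the bins;
#'   \item compute the mean bin count over that quarter;
#'   \item bins with counts above the mean form the background peak;
#'   \item a second above-mean peak is merged into the background iff the
#'     gap to the first peak is smaller than \code{peak_gap} bins (a CT
#'     table in the background yields a nearby second peak that belongs to
#'     the background; a weakly separated foreground peak lies further
#'     away);
#'   \item from the rightmost background-peak bin, scan right to the first
#'     local minimum of the counts (count at most that of both neighbors,
#'     leftmost such bin);
#'   \item the threshold is the left edge of that minimum bin.
#' }
#'
#' @param projection Numeric matrix of line-integral values.
#' @param bin_width Histogram bin width in line-integral units (default 0.02).
#' @param peak_gap Maximum number of bins between two low-value peaks for
#'   them to be merged into one background region (default 10).
#' @return List with \code{threshold}, \code{flag} (\code{"ok"},
#'   \code{"no_background"} when no above-mean peak exists in the lower
#'   quarter, or \code{"no_minimum"} when the counts never reach a local
#'   minimum right of the peak), and the histogram (\code{breaks},
#'   \code{counts}).
#' @export
find_background_threshold <- function(projection, bin_width = 0.02,
                                      peak_gap = 10) {
  x <- as.numeric(projection)
  lo <- min(x)
  hi <- max(x)
  n_bins <- ceiling((hi - lo) / bin_width)
  if (!is.finite(n_bins) || n_bins < 2)
    stop("degenerate histogram: projection values span less than two bins")
  breaks <- lo + (0:n_bins) * bin_width
  counts <- tabulate(pmin(floor((x - lo) / bin_width) + 1L, n_bins), n_bins)
  quarter <- seq_len(ceiling(n_bins / 4))
  mean_count <- mean(counts[quarter])
  above <- counts[quarter] > mean_count
  if (!any(above))
    return(list(threshold = lo, flag = "no_background",
                breaks = breaks, counts = counts))
  # runs of above-mean bins in the lower quarter; merge close peaks
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peak_runs <- which(r$values)
  bg_end <- ends[peak_runs[1]]
  if (length(peak_runs) > 1) {
    # a single additional low-value peak (e.g. a CT table) may merge into
    # the background when it is close enough; further peaks never do
    j <- peak_runs[2]
    gap <- starts[j] - bg_end - 1     # bins strictly between the two peaks
    if (gap < peak_gap) bg_end <- ends[j]
  }
  # first local minimum right of the background peak
  flag <- "no_minimum"
  minimum <- n_bins
  for (j in seq(bg_end + 1, length.out = max(0, n_bins - bg_end - 1))) {
    right <- if (j + 1 <= n_bins) counts[j + 1] else Inf
    if (counts[j] <= counts[j - 1] && counts[j] <= right) {
      minimum <- j
      flag <- "ok"
      break
    }
  }
  list(threshold = breaks[minimum], flag = flag,
       breaks = breaks, counts = counts)
}

#' Complementary AEC / low-dose masks of one projection
#'
#' The AEC mask keeps pixels above the background threshold; per detector
#' row, runs of kept pixels shorter than \code{min_run} are set to zero to
#' remove speckle.  The low-dose mask is the logical complement of the
#' despeckled AEC mask.
#'
#' @param projection Numeric matrix (line integrals).
#' @param threshold Background threshold, from
#'   [find_background_threshold()].
#' @param min_run Minimum kept run length per row in pixels (default 5;
#'   runs of width less than this are removed).
#' @return List with binary (0/1) integer matrices \code{aec_mask} and
#'   \code{lowdose_mask}.
#' @export
make_masks <- function(projection, threshold, min_run = 5) {
  aec <- projection > threshold
  for (r in seq_len(nrow(aec))) {
    rl <- rle(aec[r, ])
    rl$values[rl$values & rl$lengths < min_run] <- FALSE
    aec[r, ] <- inverse.rle(rl)
  }
  list(aec_mask = aec + 0L, lowdose_mask = 1L - (aec + 0L))
}

#' Per-view mask stack of an AEC scan
#'
#' Runs [find_background_threshold()] and [make_masks()] on every view in
#' \code{correction_views}; views outside the correction set get an all-ones
#' AEC mask (they are left unaltered by the combination).  Views whose
#' histogram yields no background peak are flagged and also left with an
#' all-ones mask.
#'
#' @param stack AEC [projection_stack()] or array.
#' @param correction_views Integer view indices (default: the lateral view
#'   range from [correction_view_set()] when a `projection_stack` carrying
#'   its geometry is given).
#' @param bin_width,peak_gap,min_run See [find_background_threshold()] and
#'   [make_masks()].
#' @return Object of class \code{mask_stack}: arrays \code{aec_mask},
#'   \code{lowdose_mask} (rows x cols x views), per-view \code{threshold}
#'   (NA outside the correction set) and logical \code{applied}.
#' @export
mask_stack <- function(stack, correction_views = NULL, bin_width = 0.02,
                       peak_gap = 10, min_run = 5) {
  data <- stack_data(stack)
  nv <- dim(data)[3]
  if (is.null(correction_views)) {
    if (!inherits(stack, "projection_stack"))
      stop("correction_views must be given for a bare array")
    correction_views <- correction_view_set(stack$geometry)
  }
  aec <- array(1L, dim(data))
  low <- array(0L, dim(data))
  thresholds <- rep(NA_real_, nv)
  applied <- rep(FALSE, nv)
  for (k in correction_views) {
    th <- find_background_threshold(data[, , k], bin_width, peak_gap)
    thresholds[k] <- th$threshold
    if (th$flag == "no_background") next  # nothing to correct in this view
    m <- make_masks(data[, , k], th$threshold, min_run)
    aec[, , k] <- m$aec_mask
    low[, , k] <- m$lowdose_mask
    applied[k] <- TRUE
  }
  structure(list(aec_mask = aec, lowdose_mask = low,
                 threshold = thresholds, applied = applied,
                 correction_views = sort(correction_views)),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("Mask stack: %d views, correction applied to %d (%s)\n",
              dim(x$aec_mask)[3], sum(x$applied),
              paste(range(x$correction_views), collapse = "..")))
  invisible(x)
}
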