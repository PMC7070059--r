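#' Mean fluorescence intensity over a region of interest
#'
#' @param intensities numeric vector or matrix of pixel intensities.
#' @param mask logical vector/matrix of the same shape selecting the ROI
#'   (default: everything).
#' @return mean of the masked intensities.
#' @export
roi_mfi <- function(intensities, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(intensities))
  if (length(mask) != length(intensities)) {
    stop("mask and intensities must have the same shape", call. = FALSE)
  }
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  v <- as.numeric(intensities)[mask]
  sum(v) / length(v)
}

#' Min-max normalization across a cohort
#'
#' (x - min) / (max - min): the cohort minimum maps to 0, the maximum to
#' 1, rank order is preserved, and the result is invariant to affine
#' transformation of the inputs.
#'
#' @param x numeric vector with at least two distinct values.
#' @return values in \[0, 1\].
#' @export
min_max_normalize <- function(x) {
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0) {
    stop("all values equal; min-max scale undefined", call. = FALSE)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Split an organ mask into distal and proximal sub-masks
#'
#' Partitions the mask pixels along the organ's long axis (the image
#' dimension in which the mask extends furthest) at the given fraction.
#' Every mask pixel lands in exactly one sub-mask, so distal + proximal
#' pixel counts always equal the whole-organ count.
#'
#' @param mask logical matrix marking the organ.
#' @param fraction position of the cut along the long axis, in (0, 1);
#'   default 0.5. The distal piece is the first `fraction` of the axis.
#' @return list with logical matrices `distal` and `proximal`.
#' @export
segment_rois <- function(mask, fraction = 0.5) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- mask != 0
  if (!any(mask)) stop("degenerate mask: no pixels", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("split fraction must be strictly inside (0, 1)", call. = FALSE)
  }
  idx <- which(mask, arr.ind = TRUE)
  span <- apply(idx, 2, function(v) diff(range(v)) + 1L)
  axis <- which.max(span)  # 1 = rows, 2 = columns
  if (span[axis] < 2L) stop("degenerate mask: no extent to split", call. = FALSE)
  lo <- min(idx[, axis])
  cut <- lo + fraction * span[axis]  # pixels with coordinate < cut are distal
  distal <- proximal <- matrix(FALSE, nrow(mask), ncol(mask))
  is_distal <- idx[, axis] < cut
  distal[idx[is_distal, , drop = FALSE]] <- TRUE
  proximal[idx[!is_distal, , drop = FALSE]] <- TRUE
  if (!any(distal) || !any(proximal)) {
    stop("split fraction leaves an empty segment", call. = FALSE)
  }
  list(distal = distal, proximal = proximal)
}

#' Percent marker-positive pixels
#'
#' Marker-stained area divided by total mucosal area, x100, as used for
#' %Iba-1(+) and %NE(+) immunohistochemistry readouts.
#'
#' @param marker_area marker-positive pixel area.
#' @param mucosal_area total mucosal pixel area (> 0, >= marker_area).
#' @return percent in \[0, 100\].
#' @export
positive_fraction <- function(marker_area, mucosal_area) {
  if (any(mucosal_area <= 0)) stop("mucosal area must be > 0", call. = FALSE)
  if (any(marker_area < 0) || any(marker_area > mucosal_area)) {
    stop("marker area must lie in [0, mucosal area]", call. = FALSE)
  }
  100 * marker_area / mucosal_area
}

#' Erosion and crypt-loss profile of a resected colon
#'
#' Positions are measured in mm proximally from the rectal squamous
#' junction (position 0). Erosions are half-open intervals
#' \[start, end); the crypt-loss profile is a step function given as
#' breakpoints with the loss fraction that applies from each breakpoint
#' up to the next (or to the end of the colon).
#'
#' @param length_mm assessed colon length (mm).
#' @param erosions data frame with columns `start_mm`, `end_mm`
#'   (possibly empty or NULL).
#' @param loss_profile data frame with columns `position_mm`
#'   (non-decreasing, first row at 0) and `loss_fraction` in \[0, 1\];
#'   NULL means no crypt loss anywhere.
#' @return object of class `erosion_profile`.
#' @export
erosion_profile <- function(length_mm, erosions = NULL, loss_profile = NULL) {
  if (!is.finite(length_mm) || length_mm <= 0) {
    stop("colon length must be > 0", call. = FALSE)
  }
  if (is.null(erosions)) {
    erosions <- data.frame(start_mm = numeric(0), end_mm = numeric(0))
  }
  if (nrow(erosions) > 0) {
    if (any(erosions$start_mm < 0) || any(erosions$end_mm > length_mm) ||
        any(erosions$end_mm <= erosions$start_mm)) {
      stop("erosion intervals must be non-empty and lie within [0, length]",
           call. = FALSE)
    }
  }
  if (is.null(loss_profile)) {
    loss_profile <- data.frame(position_mm = 0, loss_fraction = 0)
  }
  if (loss_profile$position_mm[1] != 0 ||
      any(diff(loss_profile$position_mm) < 0) ||
      any(loss_profile$loss_fraction < 0 | loss_profile$loss_fraction > 1)) {
    stop("loss profile must start at 0, be ordered, with fractions in [0, 1]",
         call. = FALSE)
  }
  structure(list(length_mm = length_mm, erosions = erosions,
                 loss_profile = loss_profile),
            class = "erosion_profile")
}

# merge possibly overlapping half-open intervals; returns matrix start/end
.merge_intervals <- function(start, end) {
  if (length(start) == 0) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Total erosion length
#'
#' Sum of erosion interval lengths after merging overlaps.
#'
#' @param profile an [erosion_profile()].
#' @return total eroded length (mm).
#' @export
total_erosion_length <- function(profile) {
  stopifnot(inherits(profile, "erosion_profile"))
  m <- .merge_intervals(profile$erosions$start_mm, profile$erosions$end_mm)
  sum(m[, "end"] - m[, "start"])
}

#' Extent of inflammation from the rectal junction
#'
#' Length of the maximal contiguous run, starting at position 0, over
#' which more than `threshold` of normal crypt architecture is lost.
#' Crypt loss that begins away from the junction does not count.
#'
#' @param profile an [erosion_profile()].
#' @param threshold crypt-loss fraction that must be exceeded
#'   (default 0.5).
#' @return extent (mm).
#' @export
inflammation_extent <- function(profile, threshold = 0.5) {
  stopifnot(inherits(profile, "erosion_profile"))
  lp <- profile$loss_profile
  for (i in seq_len(nrow(lp))) {
    if (lp$loss_fraction[i] <= threshold) {
      return(lp$position_mm[i])
    }
  }
  profile$length_mm
}
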