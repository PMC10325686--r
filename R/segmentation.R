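#' @useDynLib scarCCT, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# TRUE if the binary mask encloses at least one background hole.
has_enclosed_hole <- function(mask) {
  m <- (mask != 0) * 1
  filled <- EBImage::fillHull(m)
  sum(filled > 0 & m == 0) > 0
}

new_myo_mask <- function(mask, slice_index = NA_integer_, ring = NA) {
  structure(list(mask = (mask != 0) * 1L, slice_index = slice_index,
                 ring = ring), class = "myo_mask")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "myo_mask")) mask$mask else (mask != 0) * 1L
}

seg_fail <- function(slice_index, why) {
  stop(sprintf("segmentation failed (slice %s): %s",
               ifelse(is.na(slice_index), "?", slice_index), why),
       call. = FALSE)
}

#' Segment the myocardium on one early-phase slice
#'
#' Delimits the myocardial searching area by a region-growing scheme with a
#' morphological contour evolution: intensities are clustered into
#' background / myocardium / blood classes; the blood pool is grown from a
#' bright central seed and hole-filled so that papillary-muscle-like bright
#' islands are assigned to the pool; the epicardial boundary is then reached
#' by evolving the pool boundary outward through tissue-intensity pixels.
#' The myocardium is the region between the two boundaries.
#'
#' @param slice_image 2-D intensity matrix (rows x cols).
#' @param blood_seed Optional `c(row, col)` seed inside the blood pool;
#'   default is the intensity-weighted centroid of the top-decile pixels.
#' @param slice_index Carried into error messages and the result.
#' @return A `myo_mask` object: binary `mask`, `slice_index`, and `ring`
#'   (TRUE if the mask fully encloses the blood pool).
#' @export
segment_myocardium <- function(slice_image, blood_seed = NULL,
                               slice_index = NA_integer_) {
  stopifnot(is.matrix(slice_image))
  rng <- range(slice_image)
  if (!all(is.finite(rng)) || diff(rng) == 0)
    seg_fail(slice_index, "uniform-intensity slice, no region to grow")
  sz <- dim(slice_image)

  # smooth for mask estimation only; patch intensities stay untouched
  sm <- as.matrix(EBImage::gblur(slice_image, sigma = 1))

  # background level from the image border (air/lung surround)
  bg_est <- stats::median(c(sm[1, ], sm[nrow(sm), ], sm[, 1], sm[, ncol(sm)]))

  if (is.null(blood_seed)) {
    # intensity-weighted centroid of the top-decile pixels
    thr_top <- stats::quantile(sm, 0.9)
    idx <- which(sm >= thr_top, arr.ind = TRUE)
    w <- sm[sm >= thr_top] - min(sm) + 1e-9
    blood_seed <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
  }
  blood_seed <- pmin(pmax(round(blood_seed), 1), sz)

  nb <- sm[max(1, blood_seed[1] - 2):min(sz[1], blood_seed[1] + 2),
           max(1, blood_seed[2] - 2):min(sz[2], blood_seed[2] + 2)]
  blood_est <- mean(nb)
  contrast <- blood_est - bg_est
  if (contrast <= 0)
    seg_fail(slice_index, "no bright blood pool above background")

  # grow the heart region (myocardium + pool) outward from the seed
  grow_heart <- function(thr) {
    tlab <- EBImage::bwlabel((sm > thr) * 1)
    heart_lab <- tlab[blood_seed[1], blood_seed[2]]
    if (heart_lab == 0) seg_fail(slice_index, "seed outside any grown region")
    EBImage::fillHull((tlab == heart_lab) * 1)
  }
  # first pass locates the region; the myocardial level it yields then
  # places the epicardial threshold midway between background and wall
  heart <- grow_heart(bg_est + 0.25 * contrast)
  if (sum(heart) < 0.01 * length(sm))
    seg_fail(slice_index, "no region satisfying the growth criterion")
  # wall level from heart pixels that are not clearly blood
  wall_px <- sm[heart > 0 & sm < (bg_est + blood_est) / 2]
  if (length(wall_px) == 0) seg_fail(slice_index, "no myocardial wall found")
  myo_est <- stats::median(wall_px)
  if (myo_est - bg_est < 0.08 * contrast ||
      blood_est - myo_est < 0.15 * contrast)
    seg_fail(slice_index, "no contrast between blood pool and myocardium")
  heart <- grow_heart((bg_est + myo_est) / 2)

  # endocardial boundary: bright core inside the heart, hole-filled so
  # papillary-muscle-like islands join the pool
  bright <- (sm > (myo_est + blood_est) / 2 & heart > 0) * 1
  blab <- EBImage::bwlabel(bright)
  pool_lab <- blab[blood_seed[1], blood_seed[2]]
  if (pool_lab == 0) {
    tab <- tabulate(blab[blab > 0])
    if (length(tab) == 0) seg_fail(slice_index, "no blood pool found")
    pool_lab <- which.max(tab)
  }
  pool <- EBImage::fillHull((blab == pool_lab) * 1)

  myo <- pmax(heart - pool, 0)
  mlab <- EBImage::bwlabel(myo)
  if (max(mlab) == 0) seg_fail(slice_index, "empty myocardium ring")
  tab <- tabulate(mlab[mlab > 0])
  myo <- (mlab == which.max(tab)) * 1

  new_myo_mask(myo, slice_index, ring = has_enclosed_hole(myo))
}

#' Accept an externally supplied myocardium mask
#'
#' Stands in for manual adjustment of the automatic contours: the mask is
#' validated (non-empty, binary) and returned unchanged, with its ring
#' topology (does it enclose a blood-pool hole?) flagged. A non-ring mask is
#' accepted but flagged `ring = FALSE`.
#'
#' @param mask Binary 2-D matrix.
#' @param slice_index Carried into the result.
#' @return A `myo_mask` object.
#' @export
accept_external_mask <- function(mask, slice_index = NA_integer_) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1)))
    stop("external mask must be binary", call. = FALSE)
  if (sum(mask) == 0)
    stop("external mask is empty", call. = FALSE)
  new_myo_mask(mask, slice_index, ring = has_enclosed_hole(mask))
}

#' Mask an image
#'
#' Multiplies the image with a binary mask: pixels outside the mask become
#' exactly 0, pixels inside are unchanged.
#'
#' @param slice_image 2-D matrix.
#' @param mask Binary 2-D matrix or `myo_mask` of the same shape.
#' @return Masked image matrix.
#' @export
apply_mask <- function(slice_image, mask) {
  m <- as_mask_matrix(mask)
  if (!identical(dim(slice_image), dim(m)))
    stop("image and mask shapes differ", call. = FALSE)
  slice_image * m
}

#' Dice similarity of two binary masks
#'
#' @param a,b Binary 2-D or 3-D arrays of identical shape.
#' @return 2|a&b| / (|a| + |b|); 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
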