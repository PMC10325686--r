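#' Preprocess one sector into a model-ready patch
#'
#' Crops the myocardium-masked slice to the sector mask's bounding box,
#' zero-pads the crop to a centered square, resamples to 85 x 85 pixels with
#' bilinear interpolation, and z-scores the result to zero mean and unit
#' (population) variance over all 85 x 85 values.
#'
#' @param masked_slice_image Myocardium-masked intensity matrix (background
#'   exactly 0, see [apply_mask()]).
#' @param sector_mask Binary matrix of the sector, same shape, non-empty.
#' @param size Output side length in pixels.
#' @return `size` x `size` numeric matrix with mean 0 and variance 1.
#' @export
preprocess_sector <- function(masked_slice_image, sector_mask, size = 85L) {
  stopifnot(identical(dim(masked_slice_image), dim(sector_mask)))
  idx <- which(sector_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty sector mask", call. = FALSE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  crop <- masked_slice_image[r0:r1, c0:c1, drop = FALSE]
  h <- nrow(crop); w <- ncol(crop)
  side <- max(h, w)
  sq <- matrix(0, side, side)
  ro <- (side - h) %/% 2; co <- (side - w) %/% 2
  sq[(ro + 1):(ro + h), (co + 1):(co + w)] <- crop
  patch <- as.matrix(EBImage::resize(sq, w = size, h = size,
                                     filter = "bilinear"))
  mu <- mean(patch)
  v <- mean((patch - mu)^2)
  if (v < 1e-12) stop("degenerate patch: zero variance", call. = FALSE)
  (patch - mu) / sqrt(v)
}

#' Undersample the majority class to a balanced ratio
#'
#' Keeps every minority-class sample and a uniformly random, seeded subset
#' of the majority class of equal size.
#'
#' @param labels Binary vector (0 = no scar, 1 = scar).
#' @param seed Integer seed.
#' @return Sorted integer indices of the kept samples.
#' @export
undersample <- function(labels, seed = 1L) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("undersampling requires both classes present", call. = FALSE)
  minority <- if (n1 <= n0) 1L else 0L
  keep_min <- which(labels == minority)
  maj <- which(labels != minority)
  keep_maj <- with_seed(seed, sample(maj, length(keep_min)))
  sort(c(keep_min, keep_maj))
}

#' Augmentation configuration
#'
#' Default ranges: rotation within +/-15 degrees, isotropic scale in
#' 0.9-1.1, translation up to 10% of width, horizontal flip with
#' probability 0.5.
#'
#' @param rotation_max Max absolute rotation, degrees.
#' @param scale_range Length-2 (low, high), both > 0.
#' @param translate_max Max absolute translation as a fraction of width.
#' @param flip Enable random horizontal flips.
#' @param seed Base seed for per-(epoch, sample) streams.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotation_max = 15, scale_range = c(0.9, 1.1),
                           translate_max = 0.1, flip = TRUE, seed = 1L) {
  stopifnot(length(scale_range) == 2, all(scale_range > 0),
            scale_range[1] <= scale_range[2])
  structure(list(rotation_max = rotation_max, scale_range = scale_range,
                 translate_max = translate_max, flip = flip,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Randomly transform a patch
#'
#' Draws a rotation, scale, translation and (optionally) horizontal flip
#' from the config ranges and applies them about the patch center with
#' bilinear resampling; the output keeps the input shape. With all ranges
#' zero and flipping off the patch is returned unchanged.
#'
#' @param patch 2-D numeric matrix.
#' @param config An [augment_config()].
#' @param seed Optional seed for this draw (e.g. derived per epoch/sample);
#'   when NULL the current RNG stream is used.
#' @return Transformed matrix, same shape.
#' @export
augment <- function(patch, config = augment_config(), seed = NULL) {
  draw <- function() {
    list(
      theta = stats::runif(1, -config$rotation_max, config$rotation_max) *
        pi / 180,
      s = stats::runif(1, config$scale_range[1], config$scale_range[2]),
      tx = stats::runif(1, -config$translate_max, config$translate_max) *
        ncol(patch),
      ty = stats::runif(1, -config$translate_max, config$translate_max) *
        nrow(patch),
      do_flip = config$flip && stats::runif(1) < 0.5
    )
  }
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- patch
  if (p$do_flip) out <- out[, ncol(out):1, drop = FALSE]  # left-right mirror
  if (p$theta != 0 || p$s != 1 || p$tx != 0 || p$ty != 0) {
    # forward map about the center: y = A (x - c) + c + t
    A <- p$s * rbind(c(cos(p$theta), -sin(p$theta)),
                     c(sin(p$theta), cos(p$theta)))
    ctr <- c(nrow(out) / 2, ncol(out) / 2)
    off <- ctr + c(p$ty, p$tx) - A %*% ctr
    m <- rbind(t(A), as.numeric(off))
    out <- as.matrix(EBImage::affine(out, m, filter = "bilinear",
                                     antialias = FALSE))
  }
  out
}

#' Persist model-ready samples
#'
#' Writes the patch array as a compressed RDS archive alongside a CSV
#' index (patient_id, aha_segment, slice_index, label, and fold when a
#' split is supplied).
#'
#' @param samples List with `patches` (list of matrices) and `meta`
#'   (data frame).
#' @param dir Output directory (created if missing).
#' @param folds Optional [make_folds()] split to record per sample.
#' @return `dir`, invisibly.
#' @export
save_samples <- function(samples, dir, folds = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- samples$meta
  if (!is.null(folds))
    meta$fold <- unname(folds$fold_of_patient[meta$patient_id])
  saveRDS(samples$patches, file.path(dir, "patches.rds"), compress = "gzip")
  utils::write.csv(meta, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' Patient-wise cross-validation folds
#'
#' Seeded random partition of the patients into `k` folds of sizes
#' differing by at most one; every sector inherits its patient's fold, so
#' no patient's data spans folds.
#'
#' @param patient_ids Character vector of (unique) patient ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A `fold_split`: list with `k` and `fold_of_patient` (named
#'   integer vector, patient -> fold in 1..k).
#' @export
make_folds <- function(patient_ids, k = 5L, seed = 1L) {
  patient_ids <- unique(patient_ids)
  n <- length(patient_ids)
  if (n < k) stop("fewer patients than folds", call. = FALSE)
  ord <- with_seed(seed, sample(patient_ids))
  fold <- rep(seq_len(k), length.out = n)
  out <- stats::setNames(fold, ord)
  structure(list(k = as.integer(k), fold_of_patient = out[patient_ids]),
            class = "fold_split")
}
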