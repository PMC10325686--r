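#' Assign slices to basal / mid / apical sections
#'
#' Splits the kept slices (ordered base to apex, index 0 = most basal) into
#' three contiguous groups of near-equal length. When the count is not a
#' multiple of 3, the extra slices go to the basal group first, then mid.
#'
#' @param kept_slice_indices Ordered integer vector of slice indices,
#'   base first.
#' @return Data frame with columns `slice_index`, `section`.
#' @export
assign_sections <- function(kept_slice_indices) {
  n <- length(kept_slice_indices)
  if (n < 3) stop("need at least 3 slices to form sections", call. = FALSE)
  b <- n %/% 3; r <- n %% 3
  sizes <- c(b + (r >= 1), b + (r >= 2), b)
  data.frame(
    slice_index = kept_slice_indices,
    section = rep(c("basal", "mid", "apical"), times = sizes),
    stringsAsFactors = FALSE
  )
}

# Centroid (row, col) about which angles are measured: the blood-pool hole
# centroid when the mask encloses one, otherwise the mask centroid.
mask_center <- function(m) {
  filled <- EBImage::fillHull(m)
  hole <- filled > 0 & m == 0
  src <- if (any(hole)) hole else m > 0
  idx <- which(src, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Is the myocardium a complete ring around the blood pool?
#'
#' Checks that the angular coverage of foreground pixels about the
#' blood-pool centroid is the full circle, allowing no gap larger than the
#' angular size of one pixel at the inner radius.
#'
#' @param mask Binary 2-D matrix or `myo_mask`.
#' @return TRUE iff angular coverage is complete.
#' @export
basal_ring_complete <- function(mask) {
  m <- as_mask_matrix(mask)
  if (sum(m) == 0) stop("empty mask", call. = FALSE)
  ctr <- mask_center(m)
  idx <- which(m > 0, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  r_inner <- max(min(r), 1)
  tol <- 2 * atan(0.5 / r_inner)  # one pixel of angular quantization
  ang <- sort(pixel_angle(idx[, 1], idx[, 2], ctr[1], ctr[2]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  max(gaps) <= tol
}

#' Exclude the apical cap
#'
#' Marks apical slices whose blood pool has vanished (mask no longer
#' encloses a background hole) as `excluded`; such slices belong to the
#' apical cap, which the 16-segment model omits.
#'
#' @param assignments Data frame from [assign_sections()].
#' @param masks Named list of `myo_mask` (or binary matrices), names =
#'   slice_index.
#' @return The assignments with cap slices re-labeled `excluded`.
#' @export
exclude_apical_cap <- function(assignments, masks) {
  for (i in seq_len(nrow(assignments))) {
    if (assignments$section[i] != "apical") next
    m <- masks[[as.character(assignments$slice_index[i])]]
    if (!has_enclosed_hole(as_mask_matrix(m)))
      assignments$section[i] <- "excluded"
  }
  assignments
}

aha_offset <- c(basal = 0L, mid = 6L, apical = 12L)

#' Divide a slice's myocardium into AHA sectors
#'
#' Basal and mid slices are divided into six 60-degree sectors, apical
#' slices into four 90-degree sectors, counted counterclockwise (in visual
#' image orientation) from `reference_angle` about the blood-pool centroid.
#' Each myocardial pixel is assigned by the angle of its center, with
#' half-open angular intervals, so the sector masks partition the
#' myocardium exactly.
#'
#' AHA segment ids follow the section: basal 1-6, mid 7-12, apical 13-16.
#'
#' @param mask `myo_mask` or binary matrix.
#' @param section `"basal"`, `"mid"` or `"apical"`.
#' @param reference_angle Start angle of sector 1 in radians; 0 = image up.
#' @param slice_index Carried into the output.
#' @return List of sector specs: `slice_index`, `section`, `aha_segment`,
#'   `angle_start`, `angle_end`, `mask`.
#' @export
sectorize_slice <- function(mask, section, reference_angle = 0,
                            slice_index = NA_integer_) {
  if (!section %in% names(aha_offset))
    stop("section must be basal, mid or apical", call. = FALSE)
  m <- as_mask_matrix(mask)
  if (sum(m) == 0) stop("empty mask", call. = FALSE)
  n_sect <- if (section == "apical") 4L else 6L
  width <- 2 * pi / n_sect
  ctr <- mask_center(m)
  idx <- which(m > 0, arr.ind = TRUE)
  ang <- pixel_angle(idx[, 1], idx[, 2], ctr[1], ctr[2])
  rel <- (ang - reference_angle) %% (2 * pi)
  bin <- pmin(floor(rel / width) + 1L, n_sect)  # guard rel == 2*pi edge
  lapply(seq_len(n_sect), function(k) {
    sm <- matrix(0L, nrow(m), ncol(m))
    sel <- idx[bin == k, , drop = FALSE]
    sm[sel] <- 1L
    list(
      slice_index = slice_index, section = section,
      aha_segment = aha_offset[[section]] + k,
      angle_start = (reference_angle + (k - 1) * width) %% (2 * pi),
      angle_end = (reference_angle + k * width) %% (2 * pi),
      mask = sm
    )
  })
}

#' Map slices between stacks of differing thickness
#'
#' Associates each target slice to the source slice whose physical interval
#' contains the target slice's center, both stacks aligned at their first
#' slice. Centers falling beyond the source extent clamp to the last source
#' slice, so the mapping always partitions the target slices.
#'
#' @param n_source,n_target Slice counts (>= 1).
#' @param source_thickness,target_thickness Slice thicknesses in mm (> 0).
#' @return Named list: for each source index (0-based, as character), the
#'   integer vector of 0-based target indices.
#' @export
map_slices <- function(n_source, source_thickness, n_target, target_thickness) {
  if (n_source < 1 || n_target < 1)
    stop("slice counts must be >= 1", call. = FALSE)
  if (source_thickness <= 0 || target_thickness <= 0)
    stop("thicknesses must be > 0", call. = FALSE)
  centers <- (seq_len(n_target) - 0.5) * target_thickness
  src <- pmin(pmax(floor(centers / source_thickness), 0), n_source - 1)
  out <- lapply(0:(n_source - 1), function(s) as.integer(which(src == s) - 1L))
  names(out) <- as.character(0:(n_source - 1))
  out
}

#' Identity slice mapping
#'
#' @param n Slice count.
#' @return Mapping sending each of the `n` slices to itself.
#' @export
identity_mapping <- function(n) {
  out <- lapply(0:(n - 1), function(s) s)
  names(out) <- as.character(0:(n - 1))
  out
}

#' Labeled sector image
#'
#' Renders a slice's sectors as one integer-labeled image (pixel value =
#' AHA segment id 1-16, 0 = background), e.g. for writing as a labeled
#' NIfTI volume.
#'
#' @param sectors List of sector specs (from [sectorize_slice()]).
#' @return Integer matrix.
#' @export
sector_label_image <- function(sectors) {
  out <- matrix(0L, nrow(sectors[[1]]$mask), ncol(sectors[[1]]$mask))
  for (s in sectors) out[s$mask == 1] <- as.integer(s$aha_segment)
  out
}

#' Tabulate sectors
#'
#' @param sectors List of sector specs (from [sectorize_slice()]).
#' @param patient_id Id column value.
#' @return Data frame: patient_id, slice_index, section, aha_segment,
#'   angle_start, angle_end, pixel_count.
#' @export
sector_table <- function(sectors, patient_id = NA_character_) {
  data.frame(
    patient_id = patient_id,
    slice_index = vapply(sectors, `[[`, 0L, "slice_index"),
    section = vapply(sectors, `[[`, "", "section"),
    aha_segment = vapply(sectors, function(s) as.integer(s$aha_segment), 0L),
    angle_start = vapply(sectors, `[[`, 0, "angle_start"),
    angle_end = vapply(sectors, `[[`, 0, "angle_end"),
    pixel_count = vapply(sectors, function(s) sum(s$mask), 0L),
    stringsAsFactors = FALSE
  )
}
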