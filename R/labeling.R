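#' Labeling configuration
#'
#' @param scar_fraction_threshold Enhanced-area fraction above which a sector
#'   is labeled scar; in (0, 1). Default 0.15.
#' @return A `labeling_config` list.
#' @export
labeling_config <- function(scar_fraction_threshold = 0.15) {
  if (!is.finite(scar_fraction_threshold) ||
      scar_fraction_threshold <= 0 || scar_fraction_threshold >= 1)
    stop("scar_fraction_threshold must be in (0, 1)", call. = FALSE)
  structure(list(scar_fraction_threshold = scar_fraction_threshold),
            class = "labeling_config")
}

#' Fraction of a sector covered by scar
#'
#' @param sector_mask Binary 2-D matrix, non-empty.
#' @param scar_mask Binary 2-D matrix of the same shape.
#' @return |scar intersect sector| / |sector|, in \[0, 1\]. Areas are pixel
#'   counts; the ratio is invariant to pixel spacing.
#' @export
scar_fraction <- function(sector_mask, scar_mask) {
  stopifnot(identical(dim(sector_mask), dim(scar_mask)))
  n <- sum(sector_mask != 0)
  if (n == 0) stop("empty sector mask", call. = FALSE)
  sum(sector_mask != 0 & scar_mask != 0) / n
}

#' Three-way sector label from the scar-area fraction
#'
#' A sector is `scar` when the traced enhanced area occupies more than the
#' threshold fraction of the sector area; `no_scar` when it contains no scar
#' at all; and `excluded` when it contains scar but below or at the
#' threshold. The exclusion band keeps ambiguous, partially covered sectors
#' out of both classes.
#'
#' @param fraction Scar-area fraction in \[0, 1\].
#' @param config A [labeling_config()].
#' @return `"scar"`, `"no_scar"` or `"excluded"`.
#' @export
label_sector <- function(fraction, config = labeling_config()) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]", call. = FALSE)
  thr <- config$scar_fraction_threshold
  if (fraction > thr) "scar" else if (fraction == 0) "no_scar" else "excluded"
}

#' Label every sector of a volume from the late-phase scar mask
#'
#' Each sector lives on an early-phase slice; the scar pixels are looked up
#' on the mapped late-phase slice(s) — the union when several late slices
#' map to the sector's slice.
#'
#' @param sectors List of sector specs (see [sectorize_slice()]).
#' @param scar_mask_late Binary 3-D array (slices x rows x cols), late phase.
#' @param mapping Slice mapping (early index, 0-based, as character ->
#'   0-based late indices), e.g. [identity_mapping()] or [map_slices()].
#' @param config A [labeling_config()].
#' @return Data frame: slice_index, section, aha_segment, scar_fraction,
#'   label.
#' @export
label_volume <- function(sectors, scar_mask_late, mapping,
                         config = labeling_config()) {
  rows <- lapply(sectors, function(sec) {
    key <- as.character(sec$slice_index)
    if (!key %in% names(mapping))
      stop("slice mapping is missing early slice ", key, call. = FALSE)
    late_idx <- mapping[[key]] + 1L  # to 1-based
    sm <- matrix(0L, dim(scar_mask_late)[2], dim(scar_mask_late)[3])
    for (s in late_idx) sm <- pmax(sm, (scar_mask_late[s, , ] != 0) * 1L)
    fr <- scar_fraction(sec$mask, sm)
    data.frame(slice_index = sec$slice_index, section = sec$section,
               aha_segment = sec$aha_segment, scar_fraction = fr,
               label = label_sector(fr, config), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
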