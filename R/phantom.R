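#' Phantom configuration
#'
#' Parameters of the synthetic short-axis cardiac CT phantom. The phantom
#' models the left ventricle as a bright blood pool surrounded by a darker
#' myocardial annulus whose radii taper toward the apex, on a zero
#' (air/lung-like) background. A scar, when present, is a wedge in angle
#' crossed with a radial band inside the myocardium, spanning a run of
#' consecutive slices; it enhances strongly in the late phase and only
#' faintly in the early phase, emulating delayed contrast enhancement.
#'
#' Intensities are in Hounsfield-unit-like arbitrary units. The default
#' early-phase scar contrast is 30% of the late-phase contrast, so the
#' early-phase signal is present but subtle.
#'
#' @param n_slices Number of short-axis slices (>= 6), ordered base to apex.
#' @param image_size Pixels per side of each (square) slice.
#' @param pixel_spacing In-plane pixel size in mm.
#' @param slice_thickness Slice spacing in mm.
#' @param blood_intensity,myo_intensity Mean intensity of blood pool and
#'   healthy myocardium.
#' @param scar_intensity_early,scar_intensity_late Mean scar intensity in the
#'   early and late phase.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0),
#'   independent per voxel and per phase.
#' @param scar_pattern One of `"none"`, `"subendocardial"`, `"transmural"`,
#'   `"midwall"`, `"subepicardial"`.
#' @param scar_angular_extent Angular width of the scar wedge in degrees,
#'   in (0, 360].
#' @param scar_slice_extent Number of consecutive slices carrying scar.
#' @param seed Integer seed; the case is fully determined by the config.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_slices = 10L,
                           image_size = 128L,
                           pixel_spacing = 0.8,
                           slice_thickness = 3,
                           blood_intensity = 400,
                           myo_intensity = 120,
                           scar_intensity_early = NULL,
                           scar_intensity_late = 260,
                           noise_sd = 10,
                           scar_pattern = "none",
                           scar_angular_extent = 90,
                           scar_slice_extent = 3L,
                           seed = 1L) {
  if (is.null(scar_intensity_early)) {
    # early-phase contrast = 30% of late-phase contrast over healthy myocardium
    scar_intensity_early <- myo_intensity +
      0.3 * (scar_intensity_late - myo_intensity)
  }
  cfg <- list(
    n_slices = as.integer(n_slices), image_size = as.integer(image_size),
    pixel_spacing = pixel_spacing, slice_thickness = slice_thickness,
    blood_intensity = blood_intensity, myo_intensity = myo_intensity,
    scar_intensity_early = scar_intensity_early,
    scar_intensity_late = scar_intensity_late,
    noise_sd = noise_sd, scar_pattern = scar_pattern,
    scar_angular_extent = scar_angular_extent,
    scar_slice_extent = as.integer(scar_slice_extent), seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

scar_patterns <- c("none", "subendocardial", "transmural", "midwall",
                   "subepicardial")

validate_phantom_config <- function(cfg) {
  if (!is.finite(cfg$n_slices) || cfg$n_slices < 6L)
    stop("invalid phantom config: n_slices must be >= 6", call. = FALSE)
  if (cfg$image_size < 32L)
    stop("invalid phantom config: image_size must be >= 32", call. = FALSE)
  if (cfg$pixel_spacing <= 0 || cfg$slice_thickness <= 0)
    stop("invalid phantom config: pixel_spacing and slice_thickness must be > 0",
         call. = FALSE)
  ints <- c(cfg$blood_intensity, cfg$myo_intensity,
            cfg$scar_intensity_early, cfg$scar_intensity_late)
  if (!all(is.finite(ints)))
    stop("invalid phantom config: intensities must be finite", call. = FALSE)
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    stop("invalid phantom config: noise_sd must be >= 0", call. = FALSE)
  if (!cfg$scar_pattern %in% scar_patterns)
    stop("invalid phantom config: scar_pattern must be one of ",
         paste(scar_patterns, collapse = ", "), call. = FALSE)
  if (cfg$scar_angular_extent <= 0 || cfg$scar_angular_extent > 360)
    stop("invalid phantom config: scar_angular_extent must be in (0, 360]",
         call. = FALSE)
  if (cfg$scar_slice_extent < 1L)
    stop("invalid phantom config: scar_slice_extent must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Construct a volume
#'
#' @param data 3-D array (slices x rows x cols) of finite intensities.
#' @param spacing Numeric length-3 vector (slice, row, col) in mm, all > 0.
#' @return A `volume` object.
#' @export
volume <- function(data, spacing) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("volume spacing must be > 0", call. = FALSE)
  if (!all(is.finite(data))) stop("volume values must be finite", call. = FALSE)
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "volume")
}

# Run the RNG under a local seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Visual-counterclockwise angle from "image up" (decreasing row), in [0, 2pi).
# dx = col - cx, dy_up = cy - row.
pixel_angle <- function(row, col, cy, cx) {
  ang <- atan2(-(col - cx), cy - row)
  (ang + 2 * pi) %% (2 * pi)
}

# Radial band of the myocardial wall for each scar pattern, as fractions of
# wall thickness measured from the endocardium.
pattern_band <- function(pattern) {
  switch(pattern,
    subendocardial = c(0, 1 / 3),
    midwall        = c(1 / 3, 2 / 3),
    subepicardial  = c(2 / 3, 1),
    transmural     = c(0, 1),
    stop("no radial band for pattern ", pattern, call. = FALSE)
  )
}

#' Generate one synthetic patient case
#'
#' Builds paired early/late short-axis volumes with ground-truth myocardium
#' and scar masks. The myocardium is a closed annulus on every slice; radii
#' taper linearly from base to apex. Scar (if any) occupies a seeded wedge of
#' `scar_angular_extent` degrees crossed with the radial band implied by
#' `scar_pattern`, on `scar_slice_extent` consecutive slices. Every scar
#' voxel is a myocardium voxel, and late-phase scar contrast is at least the
#' early-phase contrast. Deterministic given the config (including its seed).
#'
#' @param config A [phantom_config()].
#' @param patient_id Identifier stored in the case.
#' @return A `phantom_case` list with elements `patient_id`, `early`, `late`
#'   (both [volume()]s), `myo_mask`, `scar_mask` (binary 3-D arrays),
#'   `base_index`, `apex_index` (1-based slice indices), `pattern`.
#' @export
generate_case <- function(config, patient_id = "P001") {
  validate_phantom_config(config)
  with_seed(config$seed, {
    n <- config$n_slices
    sz <- config$image_size
    # slight seeded jitter of the LV axis keeps cases from being identical
    cy <- sz / 2 + stats::runif(1, -2, 2)
    cx <- sz / 2 + stats::runif(1, -2, 2)
    # epicardial / endocardial radii taper toward the apex
    r_epi_base <- 0.34 * sz
    r_epi_apex <- 0.17 * sz
    wall_base <- 0.11 * sz
    wall_apex <- 0.08 * sz
    fr <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
    r_epi <- r_epi_base + (r_epi_apex - r_epi_base) * fr
    r_endo <- pmax(r_epi - (wall_base + (wall_apex - wall_base) * fr), 2)

    rows <- matrix(seq_len(sz), sz, sz)
    cols <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
    rad <- sqrt((rows - cy)^2 + (cols - cx)^2)
    ang <- pixel_angle(rows, cols, cy, cx)

    myo <- array(0L, c(n, sz, sz))
    scar <- array(0L, c(n, sz, sz))
    early <- array(0, c(n, sz, sz))
    late <- array(0, c(n, sz, sz))

    has_scar <- config$scar_pattern != "none"
    if (has_scar) {
      theta0 <- stats::runif(1, 0, 2 * pi)
      width <- config$scar_angular_extent * pi / 180
      ext <- min(config$scar_slice_extent, n)
      s0 <- sample.int(n - ext + 1L, 1L)
      scar_slices <- s0:(s0 + ext - 1L)
      band <- pattern_band(config$scar_pattern)
    }

    for (s in seq_len(n)) {
      pool_s <- rad <= r_endo[s]
      myo_s <- rad > r_endo[s] & rad <= r_epi[s]
      img <- matrix(0, sz, sz)
      img[pool_s] <- config$blood_intensity
      img[myo_s] <- config$myo_intensity
      early_s <- img
      late_s <- img
      if (has_scar && s %in% scar_slices) {
        dth <- (ang - theta0) %% (2 * pi)
        wall_fr <- (rad - r_endo[s]) / (r_epi[s] - r_endo[s])
        scar_s <- myo_s & dth <= width &
          wall_fr > band[1] & wall_fr <= band[2]
        scar[s, , ][scar_s] <- 1L
        early_s[scar_s] <- config$scar_intensity_early
        late_s[scar_s] <- config$scar_intensity_late
      }
      myo[s, , ][myo_s] <- 1L
      if (config$noise_sd > 0) {
        early_s <- early_s + stats::rnorm(sz * sz, 0, config$noise_sd)
        late_s <- late_s + stats::rnorm(sz * sz, 0, config$noise_sd)
      }
      early[s, , ] <- early_s
      late[s, , ] <- late_s
    }

    sp <- c(config$slice_thickness, config$pixel_spacing, config$pixel_spacing)
    structure(list(
      patient_id = patient_id,
      early = volume(early, sp), late = volume(late, sp),
      myo_mask = myo, scar_mask = scar,
      base_index = 1L, apex_index = n,
      pattern = config$scar_pattern
    ), class = "phantom_case")
  })
}

#' Generate a synthetic cohort
#'
#' Produces `n_patients` cases with unique ids. A seeded random subset of
#' `round(n_patients * scar_prevalence)` patients receives a scar, its
#' pattern drawn uniformly from the four supported patterns (or taken from
#' `base_config$scar_pattern` when that is not `"none"`). Per-case seeds are
#' derived deterministically from `seed`, so the cohort is reproducible.
#'
#' @param n_patients Number of cases (>= 1).
#' @param base_config Template [phantom_config()]; per-case seed and pattern
#'   are overridden.
#' @param scar_prevalence Fraction of patients with scar, in \[0, 1\].
#' @param seed Cohort-level seed.
#' @return List of `phantom_case` objects.
#' @export
generate_cohort <- function(n_patients, base_config = phantom_config(),
                            scar_prevalence = 0.3, seed = 1L) {
  stopifnot(n_patients >= 1)
  if (scar_prevalence < 0 || scar_prevalence > 1)
    stop("scar_prevalence must be in [0, 1]", call. = FALSE)
  n_scar <- round(n_patients * scar_prevalence)
  with_seed(seed, {
    scar_idx <- if (n_scar > 0) sample.int(n_patients, n_scar) else integer(0)
    pool <- setdiff(scar_patterns, "none")
    patterns <- rep("none", n_patients)
    patterns[scar_idx] <- if (base_config$scar_pattern != "none")
      base_config$scar_pattern else sample(pool, n_scar, replace = TRUE)
    case_seeds <- (as.integer(seed) + 7919L * seq_len(n_patients)) %%
      2147483647L
    lapply(seq_len(n_patients), function(i) {
      cfg <- base_config
      cfg$scar_pattern <- patterns[i]
      cfg$seed <- case_seeds[i]
      validate_phantom_config(cfg)
      generate_case(cfg, patient_id = sprintf("P%03d", i))
    })
  })
}

#' Write a phantom case to NIfTI files
#'
#' Writes `early.nii.gz`, `late.nii.gz`, `myo_mask.nii.gz`,
#' `scar_mask.nii.gz` under `dir/<patient_id>/`.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if missing).
#' @return The case directory, invisibly.
#' @export
write_case_nifti <- function(case, dir) {
  out <- file.path(dir, case$patient_id)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  # NIfTI stores x,y,z: put slice last
  tonii <- function(a, sp) {
    img <- RNifti::asNifti(aperm(a, c(3, 2, 1)))
    RNifti::pixdim(img) <- c(sp[3], sp[2], sp[1])
    img
  }
  sp <- case$early$spacing
  RNifti::writeNifti(tonii(case$early$data, sp), file.path(out, "early.nii.gz"))
  RNifti::writeNifti(tonii(case$late$data, sp), file.path(out, "late.nii.gz"))
  RNifti::writeNifti(tonii(case$myo_mask, sp), file.path(out, "myo_mask.nii.gz"))
  RNifti::writeNifti(tonii(case$scar_mask, sp), file.path(out, "scar_mask.nii.gz"))
  invisible(out)
}

#' Read a volume from a NIfTI file into slice-major orientation
#'
#' @param path NIfTI file path.
#' @return A [volume()] with data as (slices x rows x cols).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  arr <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
  volume(arr, spacing = c(pd[3], pd[2], pd[1]))
}

#' Write a cohort manifest
#'
#' @param cases List of `phantom_case` objects.
#' @param path CSV output path.
#' @return The manifest data frame, invisibly.
#' @export
write_cohort_manifest <- function(cases, path) {
  df <- data.frame(
    patient_id = vapply(cases, `[[`, "", "patient_id"),
    pattern = vapply(cases, `[[`, "", "pattern"),
    n_slices = vapply(cases, function(cs) dim(cs$early$data)[1], 0L),
    scar_voxels = vapply(cases, function(cs) sum(cs$scar_mask), 0L)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
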