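test_that("config validation names the offending field", {
  expect_error(phantom_config(n_slices = 4), "n_slices")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
  expect_error(phantom_config(scar_angular_extent = 0), "scar_angular_extent")
  expect_error(phantom_config(scar_pattern = "weird"), "scar_pattern")
  expect_error(phantom_config(blood_intensity = Inf), "intensities")
})

test_that("no-scar case has an empty scar mask and a closed annulus per slice", {
  case <- generate_case(test_phantom_config(scar_pattern = "none"))
  expect_true(all(case$scar_mask == 0))
  for (s in case$base_index:case$apex_index) {
    m <- case$myo_mask[s, , ]
    expect_gt(sum(m), 0)
    expect_true(basal_ring_complete(m))
  }
})

test_that("generation is deterministic given the seed", {
  cfg <- test_phantom_config(scar_pattern = "midwall")
  expect_identical(generate_case(cfg), generate_case(cfg))
  cfg2 <- test_phantom_config(scar_pattern = "midwall", seed = 12L)
  expect_false(identical(generate_case(cfg)$early$data,
                         generate_case(cfg2)$early$data))
})

test_that("scar is always inside the myocardium, with late contrast >= early", {
  for (pat in c("subendocardial", "transmural", "midwall", "subepicardial")) {
    cfg <- test_phantom_config(scar_pattern = pat, noise_sd = 1)
    case <- generate_case(cfg)
    expect_true(all(case$scar_mask <= case$myo_mask), info = pat)
    expect_gt(sum(case$scar_mask), 0)
    scar <- case$scar_mask == 1
    healthy <- case$myo_mask == 1 & !scar
    late_contrast <- mean(case$late$data[scar]) - mean(case$late$data[healthy])
    early_contrast <- mean(case$early$data[scar]) -
      mean(case$early$data[healthy])
    expect_gte(late_contrast, early_contrast)
    # at low noise the late contrast realizes at least half its configured value
    expect_gt(abs(late_contrast),
              0.5 * abs(cfg$scar_intensity_late - cfg$myo_intensity))
  }
})

test_that("transmural 90-degree scar forms a full-thickness wedge", {
  cfg <- test_phantom_config(scar_pattern = "transmural", noise_sd = 0,
                             scar_angular_extent = 90, seed = 5L)
  case <- generate_case(cfg)
  affected <- which(apply(case$scar_mask, 1, sum) > 0)
  expect_gte(length(affected), 1)
  for (s in affected) {
    myo <- case$myo_mask[s, , ]
    scar <- case$scar_mask[s, , ]
    hole <- EBImage::fillHull(myo) > 0 & myo == 0
    ctr <- c(mean(which(hole, arr.ind = TRUE)[, 1]),
             mean(which(hole, arr.ind = TRUE)[, 2]))
    idx <- which(scar == 1, arr.ind = TRUE)
    ang <- angle_map_oracle(nrow(myo), ctr[1], ctr[2])[idx]
    rad <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
    myo_idx <- which(myo == 1, arr.ind = TRUE)
    myo_rad <- sqrt((myo_idx[, 1] - ctr[1])^2 + (myo_idx[, 2] - ctr[2])^2)
    # angular span: 90 degrees up to one pixel of angular quantization
    gaps <- diff(c(sort(ang), min(ang) + 2 * pi))
    span <- 2 * pi - max(gaps)
    quant <- 2 / min(rad)
    expect_lte(span, pi / 2 + 2 * quant)
    expect_gte(span, pi / 2 - 2 * quant)
    # transmural: spans endocardium to epicardium
    expect_lte(min(rad) - min(myo_rad), 1.5)
    expect_lte(max(myo_rad) - max(rad), 1.5)
  }
})

test_that("cohort prevalence and reproducibility behave as configured", {
  base <- test_phantom_config()
  all_clear <- generate_cohort(10, base, scar_prevalence = 0, seed = 3)
  expect_true(all(vapply(all_clear, function(cs) sum(cs$scar_mask) == 0, TRUE)))
  all_scar <- generate_cohort(10, base, scar_prevalence = 1, seed = 3)
  expect_true(all(vapply(all_scar, function(cs) sum(cs$scar_mask) > 0, TRUE)))
  ids <- vapply(all_scar, `[[`, "", "patient_id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_identical(generate_cohort(10, base, 0.5, seed = 9),
                   generate_cohort(10, base, 0.5, seed = 9))
})

test_that("a 50-patient cohort at 30% prevalence has 15 scar cases", {
  base <- test_phantom_config(n_slices = 6L, image_size = 48L)
  cohort <- generate_cohort(50, base, scar_prevalence = 0.3, seed = 2)
  n_scar <- sum(vapply(cohort, function(cs) cs$pattern != "none", TRUE))
  expect_equal(n_scar, 15L)
})

test_that("NIfTI round trip preserves voxel data and spacing", {
  case <- generate_case(test_phantom_config(image_size = 48L))
  dir <- withr::local_tempdir()
  write_case_nifti(case, dir)
  back <- read_volume_nifti(file.path(dir, case$patient_id, "early.nii.gz"))
  expect_equal(back$data, case$early$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$spacing, case$early$spacing, tolerance = 1e-6)
  manifest <- write_cohort_manifest(list(case), file.path(dir, "manifest.csv"))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(manifest$patient_id, case$patient_id)
})
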