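test_that("section assignment splits slices into near-equal contiguous groups", {
  a9 <- assign_sections(0:8)
  expect_equal(unname(table(a9$section)[c("basal", "mid", "apical")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  a3 <- assign_sections(0:2)
  expect_equal(a3$section, c("basal", "mid", "apical"))
  # remainder slices go to basal, then mid
  a11 <- assign_sections(0:10)
  expect_equal(as.vector(table(a11$section)[c("basal", "mid", "apical")]),
               c(4L, 4L, 3L))
  expect_equal(a11$section, rep(c("basal", "mid", "apical"), c(4, 4, 3)))
  expect_error(assign_sections(0:1), "at least 3")
})

test_that("ring completeness matches a brute-force angular histogram", {
  ring_oracle <- function(m, tol_deg = NULL) {
    ctr <- c(mean(which(m > 0, arr.ind = TRUE)[, 1]),
             mean(which(m > 0, arr.ind = TRUE)[, 2]))
    idx <- which(m > 0, arr.ind = TRUE)
    ang <- sort(angle_map_oracle(nrow(m), ctr[1], ctr[2])[idx])
    r_inner <- min(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
    tol <- 2 * atan(0.5 / max(r_inner, 1))
    max(diff(c(ang, ang[1] + 2 * pi))) <= tol
  }
  full <- make_annulus(64, 12, 22)
  expect_true(basal_ring_complete(full))
  expect_true(ring_oracle(full))
  wedge_gone <- make_annulus(64, 12, 22, ang_drop = c(1, 1 + pi / 6))
  expect_false(basal_ring_complete(wedge_gone))
  expect_false(ring_oracle(wedge_gone))
  # a radial slit wider than one pixel of angular quantization at r_inner
  slit <- make_annulus(64, 12, 22, ang_drop = c(2, 2 + 1.8 / 12))
  expect_false(basal_ring_complete(slit))
  expect_false(ring_oracle(slit))
  expect_error(basal_ring_complete(matrix(0, 8, 8)), "empty")
})

test_that("apical cap slices (no blood pool) are excluded", {
  ann <- make_annulus(64, 10, 20)
  disk <- make_annulus(64, -1, 14)
  masks <- list("0" = ann, "1" = ann, "2" = ann, "3" = ann,
                "4" = ann, "5" = disk)
  a <- exclude_apical_cap(assign_sections(0:5), masks)
  expect_equal(a$section[6], "excluded")
  expect_equal(a$section[5], "apical")
  # all-apical solid: whole apical group drops out
  masks2 <- masks
  masks2[["5"]] <- disk
  masks2[["4"]] <- disk
  a2 <- exclude_apical_cap(assign_sections(0:5), masks2)
  expect_false("apical" %in% a2$section)
})

test_that("sector counts are 6 (basal/mid) and 4 (apical) and partition the mask", {
  m <- make_annulus(96, 15, 30)
  for (sec in c("basal", "mid", "apical")) {
    secs <- sectorize_slice(m, sec, reference_angle = 0.3)
    expect_length(secs, if (sec == "apical") 4L else 6L)
    overlap <- Reduce(`+`, lapply(secs, `[[`, "mask"))
    expect_lte(max(overlap), 1L)              # pairwise disjoint
    expect_identical((overlap > 0) * 1L, m * 1L)  # union = myocardium
  }
  expect_error(sectorize_slice(matrix(0, 8, 8), "basal"), "empty")
  expect_error(sectorize_slice(m, "septal"), "basal, mid or apical")
})

test_that("one basal + one mid + one apical slice cover all 16 AHA segments", {
  m <- make_annulus(64, 10, 20)
  ids <- c(
    vapply(sectorize_slice(m, "basal"), `[[`, 0, "aha_segment"),
    vapply(sectorize_slice(m, "mid"), `[[`, 0, "aha_segment"),
    vapply(sectorize_slice(m, "apical"), `[[`, 0, "aha_segment"))
  expect_setequal(ids, 1:16)
})

test_that("sectors of a symmetric annulus have near-equal pixel counts", {
  m <- make_annulus(128, 35, 55)
  counts <- vapply(sectorize_slice(m, "mid"), function(s) sum(s$mask), 0L)
  expect_lte(diff(range(counts)) / mean(counts), 0.02)
})

test_that("sectorization is equivariant under quarter-turn rotation", {
  # asymmetric fixture: annulus with a bump
  m <- make_annulus(101, 15, 30)
  m[20:28, 45:55] <- 1L
  rot_ccw <- function(x) t(x)[ncol(x):1, ]  # visual 90-degree rotation
  ref <- 0.2
  c1 <- vapply(sectorize_slice(m, "mid", ref), function(s) sum(s$mask), 0L)
  c2 <- vapply(sectorize_slice(rot_ccw(m), "mid", ref + pi / 2),
               function(s) sum(s$mask), 0L)
  expect_equal(c1, c2)
})

test_that("slice mapping follows interval-center containment and partitions", {
  m <- map_slices(2, 8, 10, 1.6)
  expect_equal(m[["0"]], 0:4)
  expect_equal(m[["1"]], 5:9)
  m1 <- map_slices(1, 8, 7, 1.0)
  expect_equal(m1[["0"]], 0:6)
  # brute force: 3 slices of 8mm vs 8 slices of 3mm
  m3 <- map_slices(3, 8, 8, 3)
  centers <- (seq_len(8) - 0.5) * 3
  oracle <- pmin(floor(centers / 8), 2)
  for (s in 0:2)
    expect_equal(m3[[as.character(s)]], which(oracle == s) - 1L)
  # partition property
  all_t <- sort(unlist(m3))
  expect_equal(all_t, 0:7, ignore_attr = TRUE)
  expect_error(map_slices(0, 8, 4, 2), ">= 1")
  expect_error(map_slices(2, 0, 4, 2), "> 0")
})

test_that("sector_table and label image summarize sector specs", {
  m <- make_annulus(64, 10, 20)
  secs <- sectorize_slice(m, "basal", 0, 3L)
  tab <- sector_table(secs, patient_id = "P001")
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$aha_segment, 1:6)
  expect_true(all(tab$pixel_count > 0))
  expect_equal(unique(tab$slice_index), 3L)
  lab <- sector_label_image(secs)
  expect_setequal(unique(as.vector(lab)), c(0L, 1:6))
  expect_identical((lab > 0) * 1L, m * 1L)
})
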