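make_labelmap <- function(labels) {
  organoidIF:::new_nuclei_labels(labels, list())
}

test_that("a single-voxel nucleus has a 6-voxel unit ring", {
  labels <- array(0L, c(7, 7, 7))
  labels[4, 4, 4] <- 1L
  zones <- build_perinuclear_zones(make_labelmap(labels),
                                   ring_width_vox = 1)
  expect_equal(unname(zones$zone_area), 6)
  expect_equal(zones$zone_labels, oracle_ring(labels, 1))
})

test_that("zone assignment matches the brute-force nearest-nucleus oracle", {
  # two nuclei close enough for their rings to compete
  labels <- array(0L, c(5, 16, 16))
  labels[2:4, 4:6, 4:6] <- 1L
  labels[2:4, 9:11, 6:8] <- 2L
  for (rw in c(1, 2, 3)) {
    zones <- build_perinuclear_zones(make_labelmap(labels),
                                     ring_width_vox = rw)
    expect_equal(zones$zone_labels, oracle_ring(labels, rw),
                 label = paste("ring width", rw))
    # zones never overlap nuclei
    expect_true(all(zones$zone_labels[labels > 0] == 0))
  }
})

test_that("well-separated nuclei get disjoint zones of their own", {
  labels <- array(0L, c(6, 24, 24))
  labels[3, 6, 6] <- 1L
  labels[3, 18, 18] <- 2L
  zones <- build_perinuclear_zones(make_labelmap(labels),
                                   ring_width_vox = 2)
  # Euclidean ball of radius 2 around a voxel holds 32 neighbours
  expect_equal(unname(zones$zone_area), c(32, 32))
  owners1 <- which(zones$zone_labels == 1, arr.ind = TRUE)
  expect_true(all(abs(owners1[, 2] - 6) <= 2 & abs(owners1[, 3] - 6) <= 2))
})

test_that("positivity is inclusive at the minimum fraction", {
  # synthetic zone of exactly 200 voxels; no geometry needed
  zone_labels <- array(0L, c(5, 10, 10))
  zone_labels[seq_len(200)] <- 1L
  zones <- structure(list(zone_labels = zone_labels,
                          zone_area = c(`1` = 200L), ring_width_vox = 2),
                     class = "perinuclear_zones")
  mask_arr <- array(FALSE, c(5, 10, 10))
  mask_arr[1:2] <- TRUE  # exactly 1% of the zone
  m <- mask_from_array(mask_arr)
  expect_equal(as.integer(classify_positive_cells(zones, m)), 1L)

  mask_arr[2] <- FALSE  # 0.5%: below the bound
  expect_length(classify_positive_cells(zones, mask_from_array(mask_arr)), 0)

  empty <- mask_from_array(array(FALSE, c(5, 10, 10)))
  expect_length(classify_positive_cells(zones, empty), 0)
})

test_that("zero-area zones are excluded and reported, not counted negative", {
  zone_labels <- array(0L, c(4, 6, 6))
  zone_labels[1:50] <- 1L
  zones <- structure(list(zone_labels = zone_labels,
                          zone_area = c(`1` = 50L, `2` = 0L),
                          ring_width_vox = 2),
                     class = "perinuclear_zones")
  mask_arr <- array(FALSE, c(4, 6, 6)); mask_arr[1:10] <- TRUE
  pos <- classify_positive_cells(zones, mask_from_array(mask_arr))
  expect_equal(as.integer(pos), 1L)
  expect_equal(attr(pos, "excluded"), 2L)
})

test_that("percent_positive handles its domain and flags the undefined case", {
  expect_equal(percent_positive(1:8, 20), 40)
  expect_equal(percent_positive(integer(0), 20), 0)
  expect_true(is.na(percent_positive(integer(0), 0)))
  expect_error(percent_positive(1:5, 3), "inconsistency")
})

test_that("pixel sums are exact and additive", {
  set.seed(77)
  m1 <- array(runif(4 * 8 * 8) < 0.3, c(4, 8, 8))
  m2 <- array(runif(4 * 8 * 8) < 0.3, c(4, 8, 8)) & !m1
  expect_equal(marker_pixel_sum(mask_from_array(m1)), sum(m1))
  expect_equal(marker_pixel_sum(mask_from_array(m1 | m2)),
               marker_pixel_sum(mask_from_array(m1)) +
                 marker_pixel_sum(mask_from_array(m2)))

  stack <- stack_from_channels(list(
    HOECHST = array(ifelse(m1, 1000, 0), dim(m1))))
  hm <- make_marker_mask(stack, "HOECHST", window_vox = c(1, 1, 1),
                         threshold_method = "fixed", fixed_threshold = 500)
  expect_equal(hoechst_pixel_sum(stack, hm), sum(m1))
  expect_error(hoechst_pixel_sum(stack, mask_from_array(m1, "TH")),
               "HOECHST")
})

test_that("fragmentation follows the cuboid closed form under 6-connectivity", {
  frag_of_cuboid <- function(a, b, c) {
    m <- array(FALSE, c(a + 4, b + 4, c + 4))
    m[3:(a + 2), 3:(b + 2), 3:(c + 2)] <- TRUE
    th_fragmentation(mask_from_array(m), 6L)
  }
  for (dims in list(c(3, 3, 3), c(3, 5, 4), c(6, 4, 8), c(10, 10, 10))) {
    a <- dims[1]; b <- dims[2]; c <- dims[3]
    expect_equal(frag_of_cuboid(a, b, c),
                 1 - (a - 2) * (b - 2) * (c - 2) / (a * b * c),
                 label = paste(dims, collapse = "x"))
  }
  # single voxel: pure surface
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(th_fragmentation(mask_from_array(single)), 1)
  # empty mask: undefined
  expect_true(is.na(th_fragmentation(
    mask_from_array(array(FALSE, c(3, 3, 3))))))
})

test_that("surface detection equals the brute-force erosion oracle", {
  set.seed(5)
  blob <- array(FALSE, c(6, 10, 10))
  blob[2:5, 3:8, 3:8] <- TRUE
  blob[sample(length(blob), 40)] <- TRUE  # roughen it
  m <- mask_from_array(blob)
  for (conn in c(6L, 26L)) {
    surf_pkg <- th_fragmentation(m, conn) * sum(blob)
    surf_oracle <- sum(blob & !oracle_erode3d(blob, conn))
    expect_equal(surf_pkg, surf_oracle, label = paste("conn", conn))
  }
})

test_that("volume-border voxels count as surface", {
  m <- array(TRUE, c(3, 3, 3))  # fills the whole volume
  expect_equal(th_fragmentation(mask_from_array(m), 6L), 26 / 27)
})

test_that("section features recover the rendered ground truth exactly", {
  sc <- clean_scene(seed = 8, n_nuclei = 8, fractions = c(GFAP = 0.5))
  rec <- section_record("H_org1", "H", 1L, sc$stack)
  f <- extract_section_features(rec)
  expect_equal(f$n_cells, 8)
  expect_equal(f$gfap_percentage,
               100 * length(sc$truth$positive_cells$GFAP) / 8)
  expect_true(is.na(f$s100b_percentage))  # channel absent
  expect_true(is.na(f$tuj1_pixels))
  expect_gt(f$th_fragmentation, 0)
  expect_lte(f$th_fragmentation, 1)

  # determinism: identical reruns
  again <- extract_section_features(rec)
  expect_identical(as.data.frame(f), as.data.frame(again))
})

test_that("an all-zero stack yields zero nuclear pixels and no cells", {
  stack <- image_stack(array(0, c(4, 16, 16, 1)), "HOECHST")
  f <- extract_section_features(section_record("o", "H", 1L, stack))
  expect_equal(f$nuclear_pixels, 0)
  expect_equal(f$n_cells, 0)
  expect_true(is.na(f$gfap_percentage))
  expect_true(is.na(f$qc_pass))
})

test_that("stage errors carry the stage name", {
  stack <- image_stack(array(1, c(2, 4, 4, 1)), "TH")
  expect_error(
    extract_section_features(section_record("o", "H", 1L, stack)),
    "\\[hoechst\\]")
})

test_that("config files override defaults and reject unknown blocks", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nuclei:", "  min_seed_distance_vox: 7",
               "classify:", "  min_fraction: 0.02"), path)
  cfg <- read_pipeline_config(path)
  expect_equal(cfg$nuclei$min_seed_distance_vox, 7)
  expect_equal(cfg$classify$min_fraction, 0.02)
  expect_equal(cfg$zones$ring_width_vox, 2)  # untouched default

  writeLines("bogus:\n  a: 1", path)
  expect_error(read_pipeline_config(path), "unknown config block")
})
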