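test_that("an empty spec renders pure background with empty ground truth", {
  sc <- render_scene(scene_spec(
    shape_vox = c(6, 24, 24), n_nuclei = 0,
    marker_positive_fraction = c(GFAP = 0.5),
    n_neurites = c(TH = 0), noise_sd = 0, seed = 1))
  expect_true(all(sc$stack$voxels ==
                    sc$stack$voxels[1, 1, 1, 1]))  # constant background
  expect_length(sc$truth$nucleus_sizes, 0)
  expect_length(sc$truth$positive_cells$GFAP, 0)
  expect_equal(sc$truth$fragment_count$TH, 0)
  expect_false(any(sc$truth$neurite_mask$TH))
})

test_that("rendering is deterministic given the seed and leaves the RNG alone", {
  sp <- scene_spec(shape_vox = c(10, 48, 48), n_nuclei = 5,
                   nucleus_radius_vox = c(mean = 3, sd = 0.3),
                   n_neurites = c(TH = 1), noise_sd = 20, seed = 99)
  set.seed(123)
  before <- .Random.seed
  a <- render_scene(sp)
  expect_identical(.Random.seed, before)  # caller's RNG untouched
  b <- render_scene(sp)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)
  c <- render_scene(update_spec(sp, seed = 100))
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("rendered nuclei count and sizes match the label volume", {
  sc <- clean_scene(seed = 4, n_nuclei = 8)
  expect_length(sc$truth$nucleus_sizes, 8)
  brute <- as.vector(table(sc$truth$nuclei_labels[sc$truth$nuclei_labels > 0]))
  expect_equal(unname(sc$truth$nucleus_sizes), brute)
  # nuclei are bright in HOECHST: every labelled voxel is foreground
  hoechst <- get_channel(sc$stack, "HOECHST")
  expect_true(all(hoechst[sc$truth$nuclei_labels > 0] > 500))
})

test_that("marker positivity follows the seeded binomial draw", {
  # the per-seed draw is reproduced exactly, and across seeds the
  # positive count behaves like Binomial(n, f)
  n <- 10; f <- 0.4
  counts <- vapply(1:120, function(seed) {
    sc <- render_scene(scene_spec(
      shape_vox = c(10, 56, 56), n_nuclei = n,
      nucleus_radius_vox = c(mean = 2.5, sd = 0.2),
      marker_positive_fraction = c(GFAP = f),
      n_neurites = integer(0), noise_sd = 0, seed = seed))
    pos <- sc$truth$positive_cells$GFAP
    expect_true(all(pos %in% seq_len(n)))
    length(pos)
  }, numeric(1))
  # mean within 4 binomial standard errors of n*f
  se <- sqrt(n * f * (1 - f) / length(counts))
  expect_lt(abs(mean(counts) - n * f), 4 * se)
  expect_gt(var(counts), 0)
})

test_that("impossible placements error instead of silently under-placing", {
  expect_error(
    render_scene(scene_spec(shape_vox = c(8, 20, 20), n_nuclei = 50,
                            nucleus_radius_vox = c(mean = 3, sd = 0),
                            noise_sd = 0, seed = 1)),
    "too small|could not place")
})

test_that("fragment counts in the ground truth follow the break level", {
  for (lvl in c(0L, 3L)) {
    sc <- render_scene(scene_spec(
      shape_vox = c(10, 128, 128), n_nuclei = 0,
      marker_positive_fraction = numeric(0),
      n_neurites = c(TH = 1), fragmentation_level = lvl,
      noise_sd = 0, seed = 2))
    expect_equal(sc$truth$fragment_count$TH, lvl + 1L)
  }
})

test_that("cohorts render one record per spec with unique identifiers", {
  base <- scene_spec(shape_vox = c(10, 48, 48), n_nuclei = 4,
                     nucleus_radius_vox = c(mean = 2.5, sd = 0.2),
                     marker_positive_fraction = c(GFAP = 0.5),
                     n_neurites = integer(0), noise_sd = 0)
  specs <- cohort_specs(base, c(H = 3, P = 3), seed = 7)
  cohort <- render_cohort(specs, sections_per_organoid = 3)
  expect_length(cohort, 6)
  lines <- vapply(cohort, function(x) x$record$line_id, character(1))
  expect_equal(lines, rep(c("H", "P"), each = 3))
  keys <- vapply(cohort, function(x)
    paste(x$record$organoid_id, x$record$section_index), character(1))
  expect_false(anyDuplicated(keys) > 0)

  # reproducible from the spec list alone
  again <- render_cohort(specs, sections_per_organoid = 3)
  expect_identical(lapply(cohort, function(x) x$record$stack$voxels),
                   lapply(again, function(x) x$record$stack$voxels))
})

test_that("duplicate seeds across a cohort are rejected", {
  sp <- scene_spec(shape_vox = c(10, 32, 32), n_nuclei = 2,
                   nucleus_radius_vox = c(mean = 2, sd = 0),
                   n_neurites = integer(0), noise_sd = 0, seed = 5)
  expect_error(render_cohort(list(H = list(sp, sp))), "distinct")
  expect_error(render_cohort(list(H = list())), "at least one")
})

test_that("per-group overrides change only the targeted group", {
  base <- scene_spec(shape_vox = c(10, 32, 32), n_nuclei = 2,
                     nucleus_radius_vox = c(mean = 2, sd = 0),
                     marker_positive_fraction = c(GFAP = 0.4),
                     n_neurites = integer(0), noise_sd = 0)
  specs <- cohort_specs(
    base, c(H = 2, P = 2),
    overrides_by_group = list(P = list(
      marker_positive_fraction = c(GFAP = 0.1))), seed = 3)
  expect_equal(specs$H[[1]]$marker_positive_fraction[["GFAP"]], 0.4)
  expect_equal(specs$P[[2]]$marker_positive_fraction[["GFAP"]], 0.1)
  seeds <- vapply(unlist(specs, recursive = FALSE),
                  function(s) s$seed, integer(1))
  expect_false(anyDuplicated(seeds) > 0)
})
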