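test_that("the QC gate removes sections strictly below the Hoechst bound", {
  f <- do.call(rbind, Map(features_row, c(4999L, 5000L, 5001L),
                          section_index = 1:3))
  res <- qc_filter(f, 5000)
  expect_equal(res$report$n_input_sections, 3L)
  expect_equal(res$report$n_passed, 2L)
  expect_equal(res$report$removed$hoechst_sum, 4999L)
  expect_equal(res$passed$nuclear_pixels, c(5000L, 5001L))
  expect_true(all(res$passed$qc_pass))
  expect_equal(res$all$qc_pass, c(FALSE, TRUE, TRUE))
  # report accounting invariant
  expect_equal(res$report$n_passed + nrow(res$report$removed),
               res$report$n_input_sections)
  # idempotent on already-filtered input
  again <- qc_filter(res$passed, 5000)
  expect_equal(again$report$n_passed, 2L)
  expect_equal(nrow(again$report$removed), 0L)
})

test_that("QC of an empty table is an empty report, not an error", {
  res <- qc_filter(features_row(1L)[0, ])
  expect_equal(res$report$n_input_sections, 0L)
  expect_equal(res$report$n_passed, 0L)
  expect_equal(nrow(res$passed), 0L)
})

test_that("QC reports serialise to JSON with their accounting intact", {
  f <- do.call(rbind, Map(features_row, c(100L, 9000L), section_index = 1:2))
  res <- qc_filter(f)
  path <- withr::local_tempfile(fileext = ".json")
  write_qc_report(res$report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_input_sections, 2L)
  expect_equal(back$n_passed, 1L)
  expect_equal(back$removed$hoechst_sum, 100L)
  expect_equal(back$threshold, 5000L)
})

test_that("aggregation by section and by organoid count points correctly", {
  f <- do.call(rbind, lapply(1:3, function(org)
    do.call(rbind, lapply(1:3, function(sec)
      features_row(6000L + 100L * org * sec,
                   organoid_id = paste0("H_org", org),
                   section_index = sec)))))
  res <- qc_filter(f)
  by_sec <- aggregate_features(res$passed, "section")
  expect_equal(nrow(by_sec), 9L)
  by_org <- aggregate_features(res$passed, "organoid")
  expect_equal(nrow(by_org), 3L)
  # each organoid point is the mean of its three sections
  m1 <- mean(f$nuclear_pixels[f$organoid_id == "H_org1"])
  expect_equal(by_org$nuclear_pixels[by_org$organoid_id == "H_org1"], m1)
  # unfiltered input is refused
  expect_error(aggregate_features(f), "qc_filter")
})

test_that("the textbook rank-sum case gives U = 0 and exact p = 0.1", {
  cmp <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$u_statistic, 0)
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$method, "exact")
  expect_equal(cmp$direction, -1)
})

test_that("the test is symmetric under group exchange", {
  set.seed(10)
  a <- rnorm(6); b <- rnorm(8) + 1
  ab <- mann_whitney(a, b)
  ba <- mann_whitney(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$u_statistic + ba$u_statistic, ab$n_a * ab$n_b)
  expect_equal(ab$direction, -ba$direction)
})

test_that("identical samples are maximally non-significant", {
  x <- c(1, 2, 3, 4)
  cmp <- mann_whitney(x, x)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$direction, 0)
})

test_that("exact p-values agree with full enumeration for all small sizes", {
  set.seed(2024)
  for (na in 1:4) for (nb in 1:4) {
    a <- sample(seq_len(100), na)
    b <- sample(setdiff(seq_len(100), a), nb)
    cmp <- mann_whitney(a, b)
    expect_equal(cmp$p_value, oracle_mw_exact(a, b),
                 label = sprintf("n_a=%d n_b=%d", na, nb))
  }
})

test_that("exact p-values agree with the independent rank-sum implementation", {
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(7); b <- rnorm(9) + 0.5
    cmp <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(cmp$p_value, ref$p.value)
    expect_equal(cmp$u_statistic, unname(ref$statistic))
  }
})

test_that("tied or large samples use the corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5, 5, 6)
  b <- c(2, 4, 5, 5, 7, 8, 9)
  cmp <- mann_whitney(a, b)
  expect_equal(cmp$method, "normal_approximation_tie_corrected")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
  expect_true(cmp$u_statistic >= 0 && cmp$u_statistic <= length(a) * length(b))
})

test_that("group comparison tables cover every requested feature", {
  set.seed(3)
  pts <- do.call(rbind, lapply(1:10, function(i) {
    r <- features_row(6000L, organoid_id = paste0("H", i),
                      line_id = if (i <= 5) "H" else "P",
                      section_index = i)
    r$gfap_percentage <- if (i <= 5) 40 + rnorm(1) else 10 + rnorm(1)
    r$qc_pass <- TRUE
    r
  }))
  cmp <- compare_groups(pts, "H", "P")
  expect_equal(nrow(cmp), 5L)
  expect_true(cmp$p_value[cmp$feature == "gfap_percentage"] < 0.05)
  expect_equal(cmp$direction[cmp$feature == "gfap_percentage"], 1)
  with_adj <- compare_groups(pts, "H", "P", bonferroni = TRUE)
  expect_true(all(with_adj$p_adjusted >= with_adj$p_value))
})
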