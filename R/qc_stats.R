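#' Quality-control gate on the Hoechst pixel sum
#'
#' Sections whose nuclear pixel sum falls below `min_hoechst_sum`
#' (strictly below; a section exactly at the bound passes) indicate
#' failed staining or imaging and are removed. Every input row gets its
#' `qc_pass` flag set; the gate is idempotent on already-filtered input.
#'
#' @param features data frame of section features (one row per section,
#'   with `nuclear_pixels` populated).
#' @param min_hoechst_sum QC bound on the Hoechst pixel sum (default
#'   5000).
#' @return a list: `passed` (tibble of passing sections, `qc_pass =
#'   TRUE`), `all` (every input section with `qc_pass` set), and
#'   `report` (a `qc_report`: input/passed counts, the removed sections
#'   with their sums, and the threshold).
#' @export
qc_filter <- function(features, min_hoechst_sum = 5000L) {
  features <- tibble::as_tibble(features)
  if (nrow(features) > 0 && anyNA(features$nuclear_pixels))
    stop("nuclear_pixels must be computed for every section before QC")
  pass <- if (nrow(features) > 0)
    features$nuclear_pixels >= min_hoechst_sum else logical(0)
  features$qc_pass <- pass
  removed <- features[!pass, c("organoid_id", "section_index",
                               "nuclear_pixels")]
  names(removed)[3] <- "hoechst_sum"
  report <- structure(
    list(n_input_sections = nrow(features), n_passed = sum(pass),
         removed = as.data.frame(removed),
         threshold = min_hoechst_sum),
    class = "qc_report")
  list(passed = features[pass, ], all = features, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d sections passed (Hoechst sum >= %d)\n",
              x$n_passed, x$n_input_sections, x$threshold))
  if (nrow(x$removed)) {
    cat("  removed:\n")
    print(x$removed, row.names = FALSE)
  }
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report` from [qc_filter()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Aggregate QC-passed sections into analysis data points
#'
#' With `unit = "section"` (the default) every passed section is one
#' data point, matching per-group section counts in the reported
#' designs; with `unit = "organoid"` each organoid contributes the mean
#' of its passed sections. Groups that lost all sections to QC are
#' dropped with a warning.
#'
#' @param features tibble of QC-passed section features.
#' @param unit `"section"` or `"organoid"`.
#' @return a tibble of data points with `line_id` as the group column.
#' @export
aggregate_features <- function(features, unit = c("section", "organoid")) {
  unit <- match.arg(unit)
  features <- tibble::as_tibble(features)
  if (nrow(features) == 0) {
    warning("no sections to aggregate")
    return(features)
  }
  if (!isTRUE(all(features$qc_pass)))
    stop("aggregate_features expects QC-passed sections; run qc_filter()")
  if (unit == "section") return(features)
  numeric_cols <- c("gfap_percentage", "s100b_percentage", "tuj1_pixels",
                    "th_fragmentation", "nuclear_pixels", "n_cells")
  dplyr::summarise(
    dplyr::group_by(features, .data$line_id, .data$organoid_id),
    dplyr::across(dplyr::all_of(numeric_cols), ~ mean(.x, na.rm = TRUE)),
    n_sections = dplyr::n(), .groups = "drop")
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' For small samples without ties (`n_a * n_b <= 400`) the p-value is
#' exact, from the null permutation distribution of the U statistic; for
#' larger samples or in the presence of ties, a normal approximation
#' with tie correction and continuity correction is used. The method
#' actually applied is recorded. Two-sided only.
#'
#' @param a,b numeric vectors, each non-empty.
#' @param feature_name optional label carried into the result.
#' @param group_a,group_b optional group labels.
#' @return a `group_comparison`: sample sizes, the U statistic (number
#'   of pairs where `a > b`, plus half the ties; `0 <= U <= n_a * n_b`),
#'   the two-sided p-value, the sign of the median difference
#'   (`median(a) - median(b)`), and the method used.
#' @export
mann_whitney <- function(a, b, feature_name = NA_character_,
                         group_a = "a", group_b = "b") {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a < 1L || n_b < 1L) stop("both groups must be non-empty")
  nm <- n_a * n_b

  r <- rank(c(a, b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L

  if (!has_ties && nm <= 400L) {
    method <- "exact"
    # null distribution of U is symmetric about nm/2
    u_low <- min(u, nm - u)
    p <- 2 * pwilcox(u_low, n_a, n_b)
    p <- min(1, p)
  } else {
    method <- "normal_approximation_tie_corrected"
    n <- n_a + n_b
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (nm / 12) * ((n + 1) - tie_term)
    mu <- nm / 2
    if (sigma2 == 0) {
      # all pooled values identical: no evidence of a difference
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
      p <- min(1, p)
    }
  }

  structure(
    list(feature_name = feature_name, group_a = group_a, group_b = group_b,
         n_a = n_a, n_b = n_b, u_statistic = u, p_value = p,
         direction = sign(median(a) - median(b)), method = method),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison>%s %s (n=%d) vs %s (n=%d): U = %g, p = %.4g (%s)\n",
    if (is.na(x$feature_name)) "" else paste0(" ", x$feature_name),
    x$group_a, x$n_a, x$group_b, x$n_b, x$u_statistic, x$p_value,
    x$method))
  invisible(x)
}

#' Compare two groups on every extracted feature
#'
#' Runs [mann_whitney()] per feature column on the aggregated data
#' points of two groups. Unadjusted per-feature p-values are reported
#' (matching the convention of per-feature testing); an optional
#' Bonferroni adjustment is available but off by default.
#'
#' @param points tibble of data points (from [aggregate_features()]).
#' @param group_a,group_b levels of `group_col` to compare.
#' @param group_col grouping column (default `"line_id"`).
#' @param feature_cols feature columns to test.
#' @param bonferroni apply Bonferroni correction across features.
#' @return a tibble with one row per feature: sample sizes, U, p-value
#'   and direction.
#' @export
compare_groups <- function(points, group_a, group_b,
                           group_col = "line_id",
                           feature_cols = c("gfap_percentage",
                                            "s100b_percentage",
                                            "tuj1_pixels",
                                            "th_fragmentation",
                                            "nuclear_pixels"),
                           bonferroni = FALSE) {
  points <- tibble::as_tibble(points)
  ga <- points[points[[group_col]] == group_a, , drop = FALSE]
  gb <- points[points[[group_col]] == group_b, , drop = FALSE]
  if (nrow(ga) == 0 || nrow(gb) == 0)
    stop("one of the groups has no data points")
  rows <- lapply(feature_cols, function(f) {
    cmp <- mann_whitney(ga[[f]], gb[[f]], feature_name = f,
                        group_a = group_a, group_b = group_b)
    data.frame(feature = f, group_a = group_a, group_b = group_b,
               n_a = cmp$n_a, n_b = cmp$n_b,
               u_statistic = cmp$u_statistic, p_value = cmp$p_value,
               direction = cmp$direction, method = cmp$method,
               stringsAsFactors = FALSE)
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  if (bonferroni)
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out
}

#' Run the full cohort pipeline
#'
#' Feature extraction on every section, the Hoechst-sum QC gate, and
#' section-level aggregation, in one call.
#'
#' @param records list of [section_record()]s or [render_cohort()]
#'   output.
#' @param config a [pipeline_config()].
#' @param unit aggregation unit, `"section"` or `"organoid"`.
#' @return list: `features` (all sections, `qc_pass` set), `points`
#'   (aggregated QC-passed data points), `qc` (the `qc_report`).
#' @export
run_pipeline <- function(records, config = pipeline_config(),
                         unit = "section") {
  feats <- extract_cohort_features(records, config)
  qc <- qc_filter(feats, config$qc$min_hoechst_sum)
  points <- aggregate_features(qc$passed, unit)
  list(features = qc$all, points = points, qc = qc$report)
}
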