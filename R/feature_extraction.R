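#' Build perinuclear zones around segmented nuclei
#'
#' For every nucleus that survived segmentation and size filtering, the
#' perinuclear zone is the set of background voxels within Euclidean
#' distance `ring_width_vox` of that nucleus, excluding all nucleus
#' voxels. A voxel within reach of two nuclei belongs to the nearer one;
#' exact ties go to the lower label. Zones are therefore pairwise
#' disjoint and disjoint from every nucleus.
#'
#' @param labelmap a `nuclei_labels` object (compacted, size-filtered).
#' @param ring_width_vox zone width in voxels (default 2: a thin shell
#'   immediately around the nucleus).
#' @return a `perinuclear_zones` object: `zone_labels` (integer array,
#'   voxel value = owning nucleus label, 0 = not in any zone) and
#'   `zone_area` (named voxel count per nucleus; may be 0 for a fully
#'   enclosed nucleus).
#' @export
build_perinuclear_zones <- function(labelmap, ring_width_vox = 2) {
  stopifnot(inherits(labelmap, "nuclei_labels"), ring_width_vox > 0)
  d <- dim(labelmap$labels)
  nlab <- length(labelmap$sizes)
  zone_labels <- if (nlab == 0L) array(0L, dim = d)
    else array(cpp_nearest_label_ring(labelmap$labels, d, ring_width_vox),
               dim = d)
  zone_area <- tabulate(zone_labels[zone_labels > 0L], nbins = nlab)
  names(zone_area) <- names(labelmap$sizes)
  structure(
    list(zone_labels = zone_labels, zone_area = zone_area,
         ring_width_vox = ring_width_vox),
    class = "perinuclear_zones")
}

#' @export
print.perinuclear_zones <- function(x, ...) {
  cat(sprintf("<perinuclear_zones> %d zones, ring width %g voxels\n",
              length(x$zone_area), x$ring_width_vox))
  invisible(x)
}

#' Classify marker-positive cells by the perinuclear rule
#'
#' A cell is positive for a marker if the marker mask covers at least
#' `min_fraction` (default 1%, inclusive) of its perinuclear zone.
#' Cells whose zone has zero area cannot be classified; they are
#' excluded and reported via the `"excluded"` attribute rather than
#' silently counted negative.
#'
#' @param zones a [build_perinuclear_zones()] result.
#' @param mask a `marker_mask` aligned to the same volume.
#' @param min_fraction inclusive positivity bound on the covered zone
#'   fraction.
#' @return sorted integer vector of positive nucleus labels, with
#'   attribute `excluded` listing zero-area labels.
#' @export
classify_positive_cells <- function(zones, mask, min_fraction = 0.01) {
  stopifnot(inherits(zones, "perinuclear_zones"),
            inherits(mask, "marker_mask"))
  if (!identical(dim(zones$zone_labels), dim(mask$mask)))
    stop("zones and mask volumes are not aligned")
  nlab <- length(zones$zone_area)
  if (nlab == 0L)
    return(structure(integer(0), excluded = integer(0)))
  overlap <- tabulate(zones$zone_labels[mask$mask], nbins = nlab)
  excluded <- which(zones$zone_area == 0L)
  classifiable <- setdiff(seq_len(nlab), excluded)
  frac <- overlap[classifiable] / zones$zone_area[classifiable]
  pos <- classifiable[frac >= min_fraction]
  structure(sort(as.integer(pos)), excluded = as.integer(excluded))
}

#' Percentage of positive cells
#'
#' `100 * n_positive / n_cells`. Undefined (returns `NA`) when there are
#' no cells to classify; an internal-consistency error if more positives
#' than cells are reported.
#'
#' @param positive vector of positive nucleus labels (or its length).
#' @param n_cells total number of classified cells.
#' @return percentage in `[0, 100]`, or `NA_real_` when `n_cells == 0`.
#' @export
percent_positive <- function(positive, n_cells) {
  npos <- length(positive)
  stopifnot(n_cells >= 0)
  if (npos > n_cells)
    stop("internal inconsistency: more positive cells (", npos,
         ") than cells (", n_cells, ")")
  if (n_cells == 0L) return(NA_real_)
  100 * npos / n_cells
}

#' Sum of positive voxels of a marker mask
#' @param mask a `marker_mask`.
#' @return integer voxel count.
#' @export
marker_pixel_sum <- function(mask) {
  stopifnot(inherits(mask, "marker_mask"))
  mask$positive_voxels
}

#' Sum of Hoechst-positive voxels of a section
#'
#' The nuclear pixel sum that feeds the section quality-control gate.
#' The Hoechst mask is produced by the same median-filter-and-threshold
#' contract as the marker masks, so QC does not depend on watershed
#' quality.
#'
#' @param stack the section's [image_stack()] (used to check alignment).
#' @param hoechst_mask a `marker_mask` with role `HOECHST`.
#' @return integer voxel count.
#' @export
hoechst_pixel_sum <- function(stack, hoechst_mask) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(hoechst_mask, "marker_mask"))
  if (hoechst_mask$role != "HOECHST")
    stop("mask role is '", hoechst_mask$role, "', expected HOECHST")
  if (!identical(dim(hoechst_mask$mask), dim(stack$voxels)[1:3]))
    stop("mask is not aligned to the stack")
  hoechst_mask$positive_voxels
}

#' Surface-to-volume fragmentation index of a binary mask
#'
#' Surface voxels are those removed by one binary erosion with the
#' chosen structuring element (6-connected cross by default, 26-connected
#' cube as an option); voxels on the volume border count as surface. The
#' index is `|surface| / |mask|`, in `(0, 1]` for a nonempty mask: a
#' single voxel is all surface (1.0), a large solid body approaches 0,
#' and breaking a structure into more pieces can only raise it.
#' Undefined (`NA`) for an empty mask.
#'
#' @param mask a `marker_mask` (typically the TH mask).
#' @param surface_connectivity 6 or 26.
#' @return fragmentation index, or `NA_real_` for an empty mask.
#' @export
th_fragmentation <- function(mask, surface_connectivity = 6L) {
  stopifnot(inherits(mask, "marker_mask"),
            surface_connectivity %in% c(6L, 26L))
  v <- mask$positive_voxels
  if (v == 0L) return(NA_real_)
  d <- dim(mask$mask)
  eroded <- cpp_erode3d(mask$mask, d, as.integer(surface_connectivity))
  surface <- v - sum(eroded)
  surface / v
}

#' Pipeline configuration
#'
#' All tunable parameters of the per-section pipeline, grouped by stage.
#' Every entry can be overridden here or from a YAML file via
#' [read_pipeline_config()]; the defaults are recorded in each result's
#' provenance.
#'
#' @param nuclei list: `sigma_vox` (`NULL` = anisotropy-scaled default),
#'   `threshold_method`, `fixed_threshold`, `watershed`,
#'   `min_seed_distance_vox`, `max_nucleus_size_vox`.
#' @param markers list: `window_vox`, `threshold_method`,
#'   `fixed_threshold`, plus optional per-role override lists under
#'   `overrides` (e.g. `overrides = list(TH = list(fixed_threshold =
#'   500))`).
#' @param zones list: `ring_width_vox`.
#' @param classify list: `min_fraction`.
#' @param fragmentation list: `surface_connectivity`.
#' @param qc list: `min_hoechst_sum`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(nuclei = list(), markers = list(),
                            zones = list(), classify = list(),
                            fragmentation = list(), qc = list()) {
  defaults <- list(
    nuclei = list(sigma_vox = NULL, threshold_method = "otsu",
                  fixed_threshold = NULL, watershed = TRUE,
                  min_seed_distance_vox = 5,
                  max_nucleus_size_vox = 10000L),
    markers = list(window_vox = c(3, 3, 3), threshold_method = "otsu",
                   fixed_threshold = NULL, overrides = list()),
    zones = list(ring_width_vox = 2),
    classify = list(min_fraction = 0.01),
    fragmentation = list(surface_connectivity = 6L),
    qc = list(min_hoechst_sum = 5000L))
  user <- list(nuclei = nuclei, markers = markers, zones = zones,
               classify = classify, fragmentation = fragmentation, qc = qc)
  for (blk in names(defaults))
    for (key in names(user[[blk]]))
      defaults[[blk]][[key]] <- user[[blk]][[key]]
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file with any subset of the [pipeline_config()]
#'   blocks.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("nuclei", "markers", "zones", "classify", "fragmentation",
             "qc")
  if (length(setdiff(names(y), known)))
    stop("unknown config block(s): ",
         paste(setdiff(names(y), known), collapse = ", "))
  do.call(pipeline_config, y)
}

marker_mask_for <- function(stack, role, cfg) {
  m <- cfg$markers
  ov <- m$overrides[[role]]
  if (!is.null(ov)) for (k in names(ov)) m[[k]] <- ov[[k]]
  make_marker_mask(stack, role, window_vox = m$window_vox,
                   threshold_method = m$threshold_method,
                   fixed_threshold = m$fixed_threshold)
}

#' Extract the per-section feature vector
#'
#' Runs the full per-section pipeline: Hoechst mask and nuclear pixel
#' sum; Gaussian preprocessing, nuclei segmentation with watershed and
#' the oversized-nucleus filter; perinuclear zones; per-cell GFAP and
#' S100B positivity; the Tuj1 pixel sum; and the TH fragmentation index.
#' Features whose channel is absent from the stack are `NA`. Errors in a
#' stage are annotated with the stage name. Deterministic for a fixed
#' record and config. The `qc_pass` flag is left `NA` here; the cohort
#' QC gate ([qc_filter()]) decides it.
#'
#' @param record a [section_record()] whose stack carries `HOECHST`.
#' @param config a [pipeline_config()].
#' @return a `section_features` object; see [write_features_table()] for
#'   the tabular form.
#' @export
extract_section_features <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "section_record"),
            inherits(config, "pipeline_config"))
  stack <- record$stack
  if (!has_channel(stack, "HOECHST"))
    stop("[hoechst] stack has no HOECHST channel")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  hoechst_mask <- stage("hoechst_mask",
                        marker_mask_for(stack, "HOECHST", config))
  nuclear_pixels <- hoechst_pixel_sum(stack, hoechst_mask)

  labelmap <- stage("nuclei_segmentation", {
    sm <- preprocess_hoechst(stack, config$nuclei$sigma_vox)
    segment_nuclei(sm,
                   threshold_method = config$nuclei$threshold_method,
                   fixed_threshold = config$nuclei$fixed_threshold,
                   watershed = config$nuclei$watershed,
                   min_seed_distance_vox =
                     config$nuclei$min_seed_distance_vox)
  })
  labelmap <- stage("size_filter",
                    filter_large_nuclei(labelmap,
                                        config$nuclei$max_nucleus_size_vox))
  ncell <- n_cells(labelmap)
  zones <- stage("perinuclear_zones",
                 build_perinuclear_zones(labelmap,
                                         config$zones$ring_width_vox))

  pct <- function(role) {
    if (!has_channel(stack, role)) return(NA_real_)
    m <- stage(paste0(tolower(role), "_mask"),
               marker_mask_for(stack, role, config))
    pos <- classify_positive_cells(zones, m, config$classify$min_fraction)
    percent_positive(pos, ncell - length(attr(pos, "excluded")))
  }
  gfap_percentage <- pct("GFAP")
  s100b_percentage <- pct("S100B")

  tuj1_pixels <- if (has_channel(stack, "TUJ1"))
    marker_pixel_sum(stage("tuj1_mask",
                           marker_mask_for(stack, "TUJ1", config)))
  else NA_integer_

  th_frag <- if (has_channel(stack, "TH"))
    th_fragmentation(stage("th_mask", marker_mask_for(stack, "TH", config)),
                     config$fragmentation$surface_connectivity)
  else NA_real_

  structure(
    list(organoid_id = record$organoid_id, line_id = record$line_id,
         section_index = record$section_index,
         gfap_percentage = gfap_percentage,
         s100b_percentage = s100b_percentage,
         tuj1_pixels = tuj1_pixels,
         th_fragmentation = th_frag,
         nuclear_pixels = nuclear_pixels,
         n_cells = ncell,
         qc_pass = NA),
    class = "section_features")
}

#' @export
print.section_features <- function(x, ...) {
  cat(sprintf(
    "<section_features> %s/%s s%d: %d cells, GFAP %s%%, S100B %s%%, Tuj1 %s px, TH frag %s, Hoechst %d px\n",
    x$organoid_id, x$line_id, x$section_index, x$n_cells,
    format(x$gfap_percentage), format(x$s100b_percentage),
    format(x$tuj1_pixels), format(x$th_fragmentation),
    x$nuclear_pixels))
  invisible(x)
}

#' @export
as.data.frame.section_features <- function(x, ...) {
  data.frame(organoid_id = x$organoid_id, line_id = x$line_id,
             section_index = x$section_index,
             gfap_percentage = x$gfap_percentage,
             s100b_percentage = x$s100b_percentage,
             tuj1_pixels = x$tuj1_pixels,
             th_fragmentation = x$th_fragmentation,
             nuclear_pixels = x$nuclear_pixels,
             n_cells = x$n_cells, qc_pass = x$qc_pass,
             stringsAsFactors = FALSE)
}

#' Extract features for every section of a cohort
#'
#' @param records a list of [section_record()]s, or the output of
#'   [render_cohort()] (records are pulled from each element).
#' @param config a [pipeline_config()].
#' @return a tibble with one row per section.
#' @export
extract_cohort_features <- function(records, config = pipeline_config()) {
  if (length(records) && is.list(records[[1]]) &&
      !inherits(records[[1]], "section_record") &&
      !is.null(records[[1]]$record))
    records <- lapply(records, `[[`, "record")
  check_unique_sections(records)
  rows <- lapply(records, function(r)
    as.data.frame(extract_section_features(r, config)))
  tibble::as_tibble(do.call(rbind, rows))
}
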