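#' Read a multi-channel 3D stack from a multi-page TIFF
#'
#' Pages are interpreted as channel-within-z interleaved grayscale planes
#' (page `(z - 1) * n_channels + c`). Stacks written by [write_stack()]
#' carry a JSON sidecar (`<path>.json`) recording the page layout, channel
#' roles and voxel size, so they are self-describing; for foreign TIFFs
#' the layout must be supplied. Axis order is normalised to
#' `(z, y, x, channel)` and integer intensities are preserved bit-exactly.
#'
#' @param path path to a TIFF file.
#' @param channel_map named integer vector mapping channel roles to
#'   1-based channel indices, e.g. `c(HOECHST = 1, TH = 2)`. Must map
#'   `HOECHST`. If `NULL`, roles are taken from the sidecar.
#' @param n_channels number of interleaved channels per z-plane; inferred
#'   from the sidecar when present.
#' @param voxel_size_um physical `(z, y, x)` spacing in micrometres;
#'   sidecar value used when present, else defaults to `c(1, 1, 1)`.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, channel_map = NULL, n_channels = NULL,
                       voxel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(n_channels))
    n_channels <- if (!is.null(meta)) meta$n_channels else
      if (!is.null(channel_map)) max(channel_map) else 1L
  n_channels <- as.integer(n_channels)
  if (is.null(voxel_size_um))
    voxel_size_um <- if (!is.null(meta)) as.numeric(meta$voxel_size_um)
      else c(1, 1, 1)

  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% n_channels != 0L)
    stop("page count ", length(pages),
         " is not a multiple of n_channels = ", n_channels)
  nz <- length(pages) %/% n_channels
  if (!all(vapply(pages, is.numeric, logical(1))))
    stop("non-numeric pixel data in ", path)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])

  vox <- array(0, dim = c(nz, ny, nx, n_channels))
  for (z in seq_len(nz)) {
    for (ch in seq_len(n_channels)) {
      p <- pages[[(z - 1L) * n_channels + ch]]
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # grayscale stored as RGB
      vox[z, , , ch] <- p
    }
  }

  roles <- rep(NA_character_, n_channels)
  if (!is.null(channel_map)) {
    idx <- as.integer(channel_map)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_channels))
      stop("channel_map index out of range 1..", n_channels)
    roles[idx] <- names(channel_map)
  } else if (!is.null(meta)) {
    roles <- as.character(meta$channel_roles)
    roles[roles == ""] <- NA_character_
  }
  if (!"HOECHST" %in% roles)
    stop("HOECHST channel must be mapped")
  image_stack(vox, roles, voxel_size_um)
}

#' Write a stack as a multi-page TIFF plus JSON sidecar
#'
#' Planes are written channel-within-z interleaved at the requested bit
#' depth; intensities must lie in `[0, 2^bits - 1]` and integer data
#' round-trip bit-exactly through [read_stack()]. The sidecar
#' (`<path>.json`) records the layout so the file is self-describing.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "image_stack"), bits %in% c(8L, 16L))
  d <- dim(stack$voxels)
  maxval <- 2^bits - 1
  if (max(stack$voxels) > maxval)
    stop("intensities exceed ", bits, "-bit range")
  pages <- vector("list", d[1] * d[4])
  for (z in seq_len(d[1]))
    for (ch in seq_len(d[4]))
      pages[[(z - 1L) * d[4] + ch]] <-
        matrix(stack$voxels[z, , , ch] / maxval, d[2], d[3])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none", reduce = FALSE)
  roles <- stack$channel_roles
  roles[is.na(roles)] <- ""
  jsonlite::write_json(
    list(n_z = d[1], n_channels = d[4], channel_roles = roles,
         voxel_size_um = stack$voxel_size_um, bits = bits,
         page_order = "channel_within_z"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Column order of the per-section feature table
#' @keywords internal
FEATURE_COLUMNS <- c(
  "organoid_id", "line_id", "section_index",
  "gfap_percentage", "s100b_percentage", "tuj1_pixels",
  "th_fragmentation", "nuclear_pixels", "n_cells", "qc_pass"
)

#' Write per-section features as CSV
#'
#' One row per section; columns are the extracted features (marker
#' percent-positive, Tuj1 pixel sum, TH fragmentation, nuclear pixel sum,
#' cell count) plus identifiers and the QC flag, in a fixed order.
#' Numeric fields round-trip through [read.csv()] at full written
#' precision.
#'
#' @param features a data frame of section features (e.g. from
#'   [extract_cohort_features()]), or a list of single-section feature
#'   objects from [extract_section_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_table <- function(features, path) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, lapply(features, as.data.frame))
  if (is.null(features) || nrow(features) == 0L)
    stop("`features` must contain at least one section")
  missing_cols <- setdiff(FEATURE_COLUMNS, names(features))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  write.csv(features[, FEATURE_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features_table()]
#' @param path CSV path.
#' @return a tibble.
#' @export
read_features_table <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
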