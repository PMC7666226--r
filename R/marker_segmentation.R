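#' 3D median filter
#'
#' Each voxel becomes the median of its `window_vox` neighbourhood
#' (whole-sample symmetric reflection at the volume boundary). Window
#' dimensions must be odd so the window is centred.
#'
#' @param vol numeric 3D array `(z, y, x)`.
#' @param window_vox window extents `(z, y, x)`, odd positive integers.
#' @return filtered array, same shape.
#' @export
median_filter <- function(vol, window_vox = c(3, 3, 3)) {
  stopifnot(length(dim(vol)) == 3L, length(window_vox) == 3L)
  window_vox <- as.integer(window_vox)
  if (any(window_vox < 1L) || any(window_vox %% 2L == 0L))
    stop("window dimensions must be odd and >= 1")
  out <- cpp_median_filter3d(as.numeric(vol), dim(vol), window_vox)
  array(out, dim = dim(vol))
}

new_marker_mask <- function(role, mask, provenance) {
  structure(
    list(role = role, mask = mask,
         positive_voxels = sum(mask), provenance = provenance),
    class = "marker_mask")
}

#' @export
print.marker_mask <- function(x, ...) {
  cat(sprintf("<marker_mask> %s: %d positive voxels of %d\n",
              x$role, x$positive_voxels, length(x$mask)))
  invisible(x)
}

#' Segment a marker channel into a boolean mask
#'
#' The marker channel (TH, GFAP, S100B, Tuj1 — or HOECHST, for the
#' nuclear pixel sum used by QC) is median filtered and thresholded:
#' `mask = filtered >= threshold`. The same operator serves all
#' channels; window and threshold are configurable per channel. Otsu is
#' the default threshold; a constant channel yields an empty mask.
#'
#' @param stack an [image_stack()].
#' @param role channel role to segment; must be present in the stack.
#' @param window_vox median window `(z, y, x)`, odd.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold when `threshold_method = "fixed"`.
#' @return a `marker_mask`: the boolean volume, the exact count of
#'   positive voxels, and the parameters used.
#' @export
make_marker_mask <- function(stack, role, window_vox = c(3, 3, 3),
                             threshold_method = c("otsu", "fixed"),
                             fixed_threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  threshold_method <- match.arg(threshold_method)
  if (!has_channel(stack, role))
    stop("channel role '", role, "' absent from stack")
  ch <- get_channel(stack, role)
  filt <- median_filter(ch, window_vox)
  thr <- switch(threshold_method,
    otsu = otsu_threshold(filt),
    fixed = {
      if (is.null(fixed_threshold)) stop("fixed_threshold required")
      fixed_threshold
    })
  mask <- if (threshold_method == "otsu" && min(filt) == max(filt))
    array(FALSE, dim = dim(filt))  # constant channel: nothing bright
  else filt >= thr
  new_marker_mask(role, mask,
                  list(window_vox = window_vox,
                       threshold_method = threshold_method,
                       threshold = thr))
}
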