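#' Separable 3D Gaussian smoothing
#'
#' Convolves a volume with a normalised, truncated (radius `3 * sigma`)
#' sampled Gaussian, one axis at a time, with whole-sample symmetric
#' (reflect) boundaries. Linear in the input, preserves constants, and
#' never produces negative values from nonnegative input.
#'
#' @param vol numeric 3D array `(z, y, x)`.
#' @param sigma_vox per-axis standard deviation in voxels `(z, y, x)`;
#'   a value of 0 skips that axis.
#' @return smoothed array, same shape.
#' @export
gaussian_blur3d <- function(vol, sigma_vox) {
  stopifnot(length(dim(vol)) == 3L, length(sigma_vox) == 3L,
            all(sigma_vox >= 0))
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0 || d[ax] == 1L) next
    K <- gauss_band_matrix(d[ax], s)
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    dim(v) <- c(d[ax], prod(d[-ax]))
    v <- K %*% v
    dim(v) <- c(d[ax], d[setdiff(1:3, ax)])
    vol <- aperm(v, order(perm))
  }
  vol
}

# n x n convolution matrix for a truncated sampled Gaussian with
# reflected (whole-sample symmetric) boundary handling; rows sum to 1
gauss_band_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq(-r, r)) {
      j <- reflect_index(i + k, n)
      K[i, j] <- K[i, j] + w[k + r + 1]
    }
  }
  K
}

reflect_index <- function(i, n) {
  if (n == 1L) return(1L)
  # reflect about 1 and n without repeating the edge sample
  while (i < 1L || i > n) {
    if (i < 1L) i <- 2L - i
    if (i > n) i <- 2L * n - i
  }
  i
}

#' Smooth the Hoechst channel for nuclei segmentation
#'
#' Image preprocessing for nuclei segmentation: the raw Hoechst channel
#' is convolved with a Gaussian. The default sigma is 2 voxels in-plane,
#' scaled by the voxel anisotropy along z (so the physical smoothing
#' scale is isotropic).
#'
#' @param stack an [image_stack()] carrying `HOECHST`.
#' @param sigma_vox per-axis sigma `(z, y, x)` in voxels, or `NULL` for
#'   the anisotropy-scaled default.
#' @return smoothed Hoechst volume (3D array).
#' @export
preprocess_hoechst <- function(stack, sigma_vox = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (!has_channel(stack, "HOECHST"))
    stop("stack has no HOECHST channel")
  if (is.null(sigma_vox)) {
    s_inplane <- 2
    s_z <- s_inplane * stack$voxel_size_um[3] / stack$voxel_size_um[1]
    sigma_vox <- c(s_z, s_inplane, s_inplane)
  }
  stopifnot(all(sigma_vox > 0))
  gaussian_blur3d(get_channel(stack, "HOECHST"), sigma_vox)
}

#' Otsu threshold of an intensity volume
#'
#' Maximises between-class variance over a 256-bin histogram of the
#' intensity range. Returns the upper edge of the chosen bin, so that
#' `x > threshold` selects the bright class. For a constant volume the
#' threshold equals that constant (nothing is selected).
#'
#' @param x numeric array or vector.
#' @param levels number of histogram bins.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  edges[k + 1L]
}

new_nuclei_labels <- function(labels, provenance) {
  labels <- array(as.integer(labels), dim = dim(labels))
  n <- if (length(labels)) max(labels) else 0L
  sizes <- tabulate(labels[labels > 0L], nbins = n)
  names(sizes) <- if (n > 0) as.character(seq_len(n)) else character(0)
  structure(list(labels = labels, sizes = sizes, provenance = provenance),
            class = "nuclei_labels")
}

#' @export
print.nuclei_labels <- function(x, ...) {
  cat(sprintf("<nuclei_labels> %d nuclei over %s voxels\n",
              length(x$sizes), paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Number of segmented nuclei
#' @param labelmap a `nuclei_labels` object.
#' @return integer count.
#' @export
n_cells <- function(labelmap) {
  stopifnot(inherits(labelmap, "nuclei_labels"))
  length(labelmap$sizes)
}

#' Segment nuclei from the smoothed Hoechst volume
#'
#' Foreground is extracted by thresholding (Otsu by default, or a fixed
#' value), then partitioned into nuclei. With `watershed = TRUE`
#' (default) touching nuclei are split: seeds are the local maxima of
#' the Euclidean distance transform of the foreground (plateau maxima
#' merged, maxima closer than `min_seed_distance_vox` suppressed keeping
#' the deeper one), and regions grow from the seeds by priority
#' flooding on the distance transform. With `watershed = FALSE`,
#' 6-connected components are the nuclei. An all-background volume
#' yields a valid empty label map.
#'
#' @param smoothed 3D array from [preprocess_hoechst()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold when `threshold_method = "fixed"`.
#' @param watershed logical; split touching nuclei.
#' @param min_seed_distance_vox minimum distance between watershed
#'   seeds, in voxels.
#' @return a `nuclei_labels` object: compacted integer labels (0 =
#'   background), exact per-label voxel counts, and the parameters used.
#' @export
segment_nuclei <- function(smoothed,
                           threshold_method = c("otsu", "fixed"),
                           fixed_threshold = NULL,
                           watershed = TRUE,
                           min_seed_distance_vox = 5) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(length(dim(smoothed)) == 3L)
  d <- dim(smoothed)
  thr <- switch(threshold_method,
    otsu = otsu_threshold(smoothed),
    fixed = {
      if (is.null(fixed_threshold)) stop("fixed_threshold required")
      fixed_threshold
    })
  fg <- smoothed > thr
  prov <- list(threshold_method = threshold_method, threshold = thr,
               watershed = watershed,
               min_seed_distance_vox = min_seed_distance_vox)
  if (!any(fg))
    return(new_nuclei_labels(array(0L, dim = d), prov))

  if (!watershed) {
    lab <- cpp_label3d(fg, d, 6L)
    return(new_nuclei_labels(lab, prov))
  }

  edt <- cpp_edt3d(fg, d, c(1, 1, 1))
  radius <- max(1L, floor(min_seed_distance_vox))
  peaks <- cpp_local_maxima3d(edt, d, radius)
  peak_lab <- cpp_label3d(peaks, d, 26L)  # plateau maxima -> one seed each
  npk <- max(peak_lab)
  if (npk == 0L) {  # degenerate: flat distance map
    lab <- cpp_label3d(fg, d, 6L)
    return(new_nuclei_labels(lab, prov))
  }
  # one representative voxel per peak component; suppress representatives
  # closer than min_seed_distance, keeping the deeper (higher EDT) one
  reps <- match(seq_len(npk), peak_lab)
  coords <- arrayInd(reps, d)
  depth <- edt[reps]
  ord <- order(-depth, seq_len(npk))
  keep <- logical(npk)
  for (i in ord) {
    ci <- coords[i, ]
    ok <- TRUE
    for (j in which(keep)) {
      if (sum((ci - coords[j, ])^2) < min_seed_distance_vox^2) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  seeds <- array(0L, dim = d)
  new_id <- cumsum(keep)
  seeds[reps[keep]] <- new_id[keep]
  lab <- cpp_watershed3d(edt, seeds, fg, d)
  new_nuclei_labels(lab, prov)
}

#' Remove oversized nuclei from a label map
#'
#' In dense tissue, merged clumps that watershed failed to split show up
#' as implausibly large "nuclei"; every label whose voxel count exceeds
#' `max_nucleus_size_vox` is removed (set to background) and the
#' remaining labels are compacted to consecutive integers. Sizes exactly
#' at the bound are retained (the removal rule is strictly "greater
#' than"). Idempotent; the removal count and removed sizes are recorded
#' in the provenance.
#'
#' @param labelmap a `nuclei_labels` object.
#' @param max_nucleus_size_vox size bound in voxels (default 10000).
#' @return a filtered `nuclei_labels` object.
#' @export
filter_large_nuclei <- function(labelmap, max_nucleus_size_vox = 10000L) {
  stopifnot(inherits(labelmap, "nuclei_labels"))
  sizes <- labelmap$sizes
  drop <- which(sizes > max_nucleus_size_vox)
  labels <- labelmap$labels
  if (length(drop)) {
    remap <- integer(length(sizes))
    kept <- setdiff(seq_along(sizes), drop)
    remap[kept] <- seq_along(kept)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  prov <- labelmap$provenance
  prov$max_nucleus_size_vox <- max_nucleus_size_vox
  prov$n_removed_oversized <- length(drop)
  prov$removed_sizes <- unname(sizes[drop])
  new_nuclei_labels(labels, prov)
}
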