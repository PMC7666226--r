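#' Specification of a synthetic organoid-section scene
#'
#' Parameterises one rendered 3D section with full ground truth: how many
#' nuclei, which fraction of cells express each perinuclear marker, how
#' many neurite tubes each neuronal channel carries and how fragmented
#' they are, plus intensity levels and a noise model. The defaults
#' emulate a 50 um vibratome section imaged by confocal microscopy:
#' 24 z-planes at 2 um spacing (48 um depth), a 96 um field at 0.6 um
#' in-plane sampling, 20 nuclei of ~8.4 um diameter per field.
#'
#' Marker positivity for GFAP/S100B is rendered as a perinuclear
#' intensity shell around the positive nucleus, because the downstream
#' classifier reads the perinuclear area; whole-cell fills would test a
#' different contract. Neurites are straight tubes; a fragmentation level
#' of `b` breaks each tube into `b + 1` pieces while keeping the total
#' kept length (hence volume, up to voxelisation) constant, so the
#' surface-to-volume fragmentation index has a controlled monotone
#' ground truth.
#'
#' @param shape_vox volume extents `(z, y, x)` in voxels.
#' @param n_nuclei number of non-overlapping ellipsoidal nuclei to place.
#' @param nucleus_radius_vox `c(mean, sd)` of the in-plane semi-axis in
#'   voxels; the z semi-axis is scaled by the voxel anisotropy.
#' @param marker_positive_fraction named vector of per-cell positive
#'   fractions in `[0, 1]` for shell markers (`GFAP`, `S100B`).
#' @param n_neurites named vector: number of neurite tubes per neuronal
#'   role (`TH`, `TUJ1`).
#' @param neurite_radius_vox tube radius in voxels.
#' @param fragmentation_level integer `>= 0`: breaks per neurite.
#' @param neurite_keep_fraction fraction of each tube's length that is
#'   rendered; constant across fragmentation levels so fragment series
#'   hold total volume fixed.
#' @param shell_width_vox width of the rendered perinuclear shell.
#' @param min_separation_vox minimum clearance between the shells of two
#'   nuclei, so that one cell's shell cannot leak into a neighbour's
#'   perinuclear zone.
#' @param intensity_levels list with `background` (scalar) and
#'   `foreground` (named per-role vector) mean intensities.
#' @param noise_sd standard deviation of additive Gaussian read noise.
#' @param poisson if `TRUE`, replace each voxel by a Poisson draw with
#'   that mean before adding Gaussian noise (shot noise).
#' @param psf_sigma_vox optional Gaussian blur `(z, y, x)` applied to the
#'   noiseless image; `0` disables it.
#' @param voxel_size_um physical voxel spacing `(z, y, x)` in um.
#' @param seed integer RNG seed; rendering is deterministic given the
#'   spec.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(shape_vox = c(24, 160, 160),
                       n_nuclei = 20,
                       nucleus_radius_vox = c(mean = 7, sd = 1),
                       marker_positive_fraction = c(GFAP = 0.4, S100B = 0.25),
                       n_neurites = c(TH = 2, TUJ1 = 2),
                       neurite_radius_vox = 4,
                       fragmentation_level = 0,
                       neurite_keep_fraction = 0.6,
                       shell_width_vox = 2,
                       min_separation_vox = 1,
                       intensity_levels = list(
                         background = 100,
                         foreground = c(HOECHST = 1000, TH = 1000,
                                        GFAP = 1000, S100B = 1000,
                                        TUJ1 = 1000)),
                       noise_sd = 45,
                       poisson = FALSE,
                       psf_sigma_vox = 0,
                       voxel_size_um = c(2, 0.6, 0.6),
                       seed = 1L) {
  spec <- list(
    shape_vox = as.integer(shape_vox), n_nuclei = as.integer(n_nuclei),
    nucleus_radius_vox = nucleus_radius_vox,
    marker_positive_fraction = marker_positive_fraction,
    n_neurites = n_neurites, neurite_radius_vox = neurite_radius_vox,
    fragmentation_level = as.integer(fragmentation_level),
    neurite_keep_fraction = neurite_keep_fraction,
    shell_width_vox = shell_width_vox,
    min_separation_vox = min_separation_vox,
    intensity_levels = intensity_levels, noise_sd = noise_sd,
    poisson = isTRUE(poisson), psf_sigma_vox = psf_sigma_vox,
    voxel_size_um = as.numeric(voxel_size_um), seed = as.integer(seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  stopifnot(length(spec$shape_vox) == 3L, all(spec$shape_vox > 0L),
            spec$n_nuclei >= 0L,
            spec$nucleus_radius_vox[["mean"]] > 0,
            spec$neurite_radius_vox > 0,
            spec$fragmentation_level >= 0L,
            spec$neurite_keep_fraction > 0,
            spec$neurite_keep_fraction <= 1,
            spec$shell_width_vox > 0,
            spec$noise_sd >= 0,
            all(spec$voxel_size_um > 0))
  f <- spec$marker_positive_fraction
  if (length(f) && (any(f < 0) || any(f > 1)))
    stop("marker_positive_fraction entries must be in [0, 1]")
  roles <- c(names(f), names(spec$n_neurites))
  if (!all(roles %in% CHANNEL_ROLES))
    stop("unknown role(s) in scene spec: ",
         paste(setdiff(roles, CHANNEL_ROLES), collapse = ", "))
  invisible(spec)
}

#' Modify a scene spec
#' @param spec a [scene_spec()].
#' @param ... fields to replace, by name.
#' @return the updated `scene_spec`.
#' @export
update_spec <- function(spec, ...) {
  stopifnot(inherits(spec, "scene_spec"))
  dots <- list(...)
  for (nm in names(dots)) spec[[nm]] <- dots[[nm]]
  do.call(scene_spec, unclass(spec))
}

# run `expr` under a scene's own RNG stream, leaving the caller's RNG
# state untouched
with_scene_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a synthetic organoid section
#'
#' Places non-overlapping ellipsoidal nuclei by rejection sampling (a
#' bounded number of retries; failure to place is an error, never
#' silent), draws per-cell marker positivity, rasterises perinuclear
#' shells and neurite tubes, composes the channel intensities, and
#' applies blur and noise last. Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return a list with `stack` (an [image_stack()] with one channel per
#'   role the spec mentions, HOECHST always present) and `truth`, a list
#'   holding `nuclei_labels` (integer array), `nucleus_sizes`,
#'   `positive_cells` (role -> nucleus labels), `neurite_mask`
#'   (role -> logical array) and `fragment_count` (role -> number of
#'   connected components of the rendered mask, 26-connectivity).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_rng(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  d <- spec$shape_vox
  zs <- spec$voxel_size_um[3] / spec$voxel_size_um[1]  # x um per z um

  ## --- nuclei placement (rejection sampling, bounded retries) ---------
  rmean <- spec$nucleus_radius_vox[["mean"]]
  rsd <- if ("sd" %in% names(spec$nucleus_radius_vox))
    spec$nucleus_radius_vox[["sd"]] else 0
  n <- spec$n_nuclei
  centers <- matrix(numeric(0), 0, 3)
  radii <- matrix(numeric(0), 0, 3)  # (rz, ry, rx)
  max_tries <- 200L * max(n, 1L)
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " non-overlapping nuclei in a ",
           paste(d, collapse = "x"), " volume after ", max_tries,
           " tries")
    r <- max(1.5, rnorm(1, rmean, rsd))
    rz <- max(1, r * zs)
    margin <- c(rz, r, r) + spec$shell_width_vox + 1
    if (any(2 * margin >= d))
      stop("volume too small for nucleus of radius ", round(r, 2))
    ctr <- runif(3, min = margin + 1, max = d - margin)
    ok <- TRUE
    if (nrow(centers) > 0) {
      extent_new <- max(rz, r) + spec$shell_width_vox
      extent_old <- apply(radii, 1, max) + spec$shell_width_vox
      dist <- sqrt(rowSums(sweep(centers, 2, ctr)^2))
      ok <- all(dist >= extent_old + extent_new + spec$min_separation_vox)
    }
    if (ok) {
      centers <- rbind(centers, ctr)
      radii <- rbind(radii, c(rz, r, r))
    }
  }

  labels <- array(0L, dim = d)
  for (i in seq_len(n)) {
    bb <- ellipsoid_bbox(centers[i, ], radii[i, ], d)
    sub <- ellipsoid_mask(centers[i, ], radii[i, ], bb)
    idx <- bbox_indices(bb, d)[sub]
    labels[idx] <- i
  }
  nucleus_sizes <- if (n > 0) tabulate(labels[labels > 0], nbins = n)
    else integer(0)

  ## --- marker positivity draws and perinuclear shells -----------------
  fractions <- spec$marker_positive_fraction
  positive_cells <- list()
  for (role in names(fractions))
    positive_cells[[role]] <-
      if (n > 0) which(rbinom(n, 1L, fractions[[role]]) == 1L)
      else integer(0)

  shell_owner <- if (n > 0)
    cpp_nearest_label_ring(labels, d, spec$shell_width_vox)
  else array(0L, dim = d)

  ## --- neurite tubes --------------------------------------------------
  neurite_mask <- list()
  fragment_count <- list()
  for (role in names(spec$n_neurites)) {
    nt <- spec$n_neurites[[role]]
    m <- array(FALSE, dim = d)
    for (j in seq_len(nt))
      m <- m | render_tube(d, spec$neurite_radius_vox,
                           spec$fragmentation_level,
                           spec$neurite_keep_fraction)
    neurite_mask[[role]] <- m
    fragment_count[[role]] <- max(cpp_label3d(m, d, 26L))
  }

  ## --- compose channels ----------------------------------------------
  roles <- unique(c("HOECHST", names(fractions), names(spec$n_neurites)))
  bg <- spec$intensity_levels$background
  fg <- spec$intensity_levels$foreground
  vox <- array(bg, dim = c(d, length(roles)))
  for (k in seq_along(roles)) {
    role <- roles[k]
    mask <- switch(role,
      HOECHST = labels > 0L,
      GFAP = ,
      S100B = {
        pos <- positive_cells[[role]]
        array(shell_owner %in% pos & shell_owner > 0L, dim = d)
      },
      TH = ,
      TUJ1 = neurite_mask[[role]])
    plane <- array(bg, dim = d)
    plane[mask] <- fg[[role]]
    if (any(spec$psf_sigma_vox > 0))
      plane <- gaussian_blur3d(plane, rep(spec$psf_sigma_vox, length.out = 3))
    vox[, , , k] <- plane
  }
  if (spec$poisson)
    vox[] <- rpois(length(vox), lambda = vox)
  if (spec$noise_sd > 0)
    vox[] <- vox + rnorm(length(vox), sd = spec$noise_sd)
  vox[vox < 0] <- 0

  stack <- image_stack(vox, roles, spec$voxel_size_um)
  truth <- list(
    nuclei_labels = labels,
    nucleus_sizes = nucleus_sizes,
    positive_cells = positive_cells,
    neurite_mask = neurite_mask,
    fragment_count = fragment_count)
  list(stack = stack, truth = truth)
}

ellipsoid_bbox <- function(ctr, rad, d) {
  lo <- pmax(1L, floor(ctr - rad))
  hi <- pmin(d, ceiling(ctr + rad))
  cbind(lo, hi)
}

bbox_indices <- function(bb, d) {
  z <- bb[1, 1]:bb[1, 2]; y <- bb[2, 1]:bb[2, 2]; x <- bb[3, 1]:bb[3, 2]
  g <- expand.grid(z = z, y = y, x = x)
  array((g$z - 1L) + d[1] * ((g$y - 1L) + d[2] * (g$x - 1L)) + 1L,
        dim = c(length(z), length(y), length(x)))
}

ellipsoid_mask <- function(ctr, rad, bb) {
  z <- bb[1, 1]:bb[1, 2]; y <- bb[2, 1]:bb[2, 2]; x <- bb[3, 1]:bb[3, 2]
  g <- expand.grid(z = z, y = y, x = x)
  v <- ((g$z - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
       ((g$x - ctr[3]) / rad[3])^2
  array(v <= 1, dim = c(length(z), length(y), length(x)))
}

# one mostly in-plane tube, broken into (fragmentation_level + 1)
# pieces of equal kept length; the whole tube (with its radius) lies
# inside the volume so no fragment is clipped away at the border
render_tube <- function(d, radius, fragmentation_level, keep_fraction) {
  mid_z <- runif(1, d[1] * 0.35, d[1] * 0.65)
  theta <- runif(1, 0, pi)
  ctr <- c(mid_z, runif(1, d[2] * 0.45, d[2] * 0.55),
           runif(1, d[3] * 0.45, d[3] * 0.55))
  dir <- c(runif(1, -0.02, 0.02), sin(theta), cos(theta))
  dir <- dir / sqrt(sum(dir^2))
  half_len <- 0.5 * min(d[2], d[3]) * 0.75 - radius - 2
  k <- fragmentation_level + 1L
  # kept sub-intervals of [0,1]: k blocks of keep/k separated by equal gaps
  block <- keep_fraction / k
  gap <- if (k > 1) (1 - keep_fraction) / (k - 1) else 0
  starts <- (seq_len(k) - 1L) * (block + gap)
  if (k == 1) starts <- (1 - keep_fraction) / 2
  m <- array(FALSE, dim = d)
  # capsule ends are inset by 2r/3 so that (in the continuum) each
  # fragment's volume is exactly pi r^2 * block-length: the spherical
  # caps add back precisely the volume the inset removes. Total rendered
  # volume is then the same for every fragment count.
  inset_t <- (2 * radius / 3) / (2 * half_len)
  block_len <- block * 2 * half_len
  if (k > 1) {
    gap_len <- gap * 2 * half_len
    if (gap_len - 2 * radius / 3 < 2)
      warning("fragment gaps (", round(gap_len, 1),
              " voxels) may be too narrow to separate fragments of ",
              "radius ", radius)
  }
  if (block_len < 2 * (2 * radius / 3) + 1)
    warning("fragment blocks (", round(block_len, 1),
            " voxels) are shorter than the capsule inset; fragments ",
            "will be undersized")
  for (b in seq_len(k)) {
    t0 <- starts[b] + inset_t
    t1 <- starts[b] + block - inset_t
    if (t1 < t0) t1 <- t0 <- starts[b] + block / 2
    p0 <- ctr + (2 * t0 - 1) * half_len * dir
    p1 <- ctr + (2 * t1 - 1) * half_len * dir
    m <- stamp_capsule(m, p0, p1, radius, d)
  }
  m
}

# voxels within `radius` of the segment p0--p1 (a capsule), clipped to
# the volume
stamp_capsule <- function(m, p0, p1, radius, d) {
  lo <- pmax(1L, floor(pmin(p0, p1) - radius))
  hi <- pmin(d, ceiling(pmax(p0, p1) + radius))
  if (any(lo > hi)) return(m)
  z <- lo[1]:hi[1]; y <- lo[2]:hi[2]; x <- lo[3]:hi[3]
  g <- expand.grid(z = z, y = y, x = x)
  v <- p1 - p0
  vv <- sum(v^2)
  wz <- g$z - p0[1]; wy <- g$y - p0[2]; wx <- g$x - p0[3]
  t <- if (vv > 0) pmin(1, pmax(0, (wz * v[1] + wy * v[2] + wx * v[3]) / vv))
    else 0
  d2 <- (wz - t * v[1])^2 + (wy - t * v[2])^2 + (wx - t * v[3])^2
  idx <- (g$z - 1L) + d[1] * ((g$y - 1L) + d[2] * (g$x - 1L)) + 1L
  m[idx[d2 <= radius^2]] <- TRUE
  m
}

#' Render a cohort of synthetic sections
#'
#' One [section_record()] per spec, grouped by cell line; ground truth is
#' kept alongside each record. Seeds must be distinct across specs so no
#' two sections are identical, and `(organoid_id, section_index)` pairs
#' are unique by construction: specs within a group are dealt into
#' organoids of `sections_per_organoid` consecutive sections.
#'
#' @param specs_by_group named list: group (line) id -> list of
#'   [scene_spec()]s, each group non-empty.
#' @param sections_per_organoid sections dealt to each organoid.
#' @return a list with one element per section, each holding `record`
#'   (a [section_record()]) and `truth` (see [render_scene()]).
#' @export
render_cohort <- function(specs_by_group, sections_per_organoid = 3L) {
  stopifnot(is.list(specs_by_group), length(specs_by_group) > 0,
            !is.null(names(specs_by_group)))
  if (any(vapply(specs_by_group, length, integer(1)) == 0L))
    stop("every group must contain at least one scene spec")
  all_specs <- unlist(specs_by_group, recursive = FALSE)
  seeds <- vapply(all_specs, function(s) s$seed, integer(1))
  if (anyDuplicated(seeds))
    stop("scene seeds must be distinct across the cohort")
  out <- list()
  for (grp in names(specs_by_group)) {
    specs <- specs_by_group[[grp]]
    for (j in seq_along(specs)) {
      org <- (j - 1L) %/% sections_per_organoid + 1L
      sec <- (j - 1L) %% sections_per_organoid + 1L
      rendered <- render_scene(specs[[j]])
      rec <- section_record(
        organoid_id = sprintf("%s_org%d", grp, org),
        line_id = grp, section_index = sec,
        stack = rendered$stack)
      out[[length(out) + 1L]] <- list(record = rec, truth = rendered$truth)
    }
  }
  check_unique_sections(lapply(out, `[[`, "record"))
  out
}

#' Build per-group spec lists with distinct derived seeds
#'
#' Convenience constructor for [render_cohort()]: replicates a base spec
#' `n` times per group, applies per-group overrides (e.g. a lower GFAP
#' fraction in the patient line), and assigns each replicate a distinct
#' seed drawn from a stream seeded by `seed`.
#'
#' @param base_spec a [scene_spec()] used as the template.
#' @param n_by_group named integer vector: group id -> number of
#'   sections.
#' @param overrides_by_group optional named list: group id -> named list
#'   of spec fields to replace for that group.
#' @param seed integer master seed.
#' @return a named list of lists of [scene_spec()]s.
#' @export
cohort_specs <- function(base_spec, n_by_group,
                         overrides_by_group = list(), seed = 1L) {
  stopifnot(inherits(base_spec, "scene_spec"), length(n_by_group) > 0,
            !is.null(names(n_by_group)))
  total <- sum(n_by_group)
  seeds <- with_scene_rng(seed, sample.int(.Machine$integer.max, total))
  out <- list()
  i <- 0L
  for (grp in names(n_by_group)) {
    ov <- overrides_by_group[[grp]]
    specs <- vector("list", n_by_group[[grp]])
    for (j in seq_len(n_by_group[[grp]])) {
      i <- i + 1L
      s <- base_spec
      if (!is.null(ov)) s <- do.call(update_spec, c(list(s), ov))
      specs[[j]] <- update_spec(s, seed = seeds[i])
    }
    out[[grp]] <- specs
  }
  out
}
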