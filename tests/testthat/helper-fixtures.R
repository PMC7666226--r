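# Fixtures and brute-force oracles shared across the test files.
# Oracles are deliberately naive (nested loops, exhaustive counting) and
# independent of the package's own kernels.

# a small clean scene: few nuclei, no noise, quick to render and segment
clean_scene <- function(seed = 1, n_nuclei = 8, fractions = c(GFAP = 0.5),
                        shape = c(10, 64, 64), noise_sd = 0, ...) {
  render_scene(scene_spec(
    shape_vox = shape, n_nuclei = n_nuclei,
    nucleus_radius_vox = c(mean = 3, sd = 0.3),
    marker_positive_fraction = fractions,
    n_neurites = c(TH = 1), noise_sd = noise_sd, seed = seed, ...))
}

# stack with given channel arrays (named by role), constant elsewhere
stack_from_channels <- function(channels, voxel_size_um = c(1, 1, 1)) {
  d <- dim(channels[[1]])
  vox <- array(0, dim = c(d, length(channels)))
  for (i in seq_along(channels)) vox[, , , i] <- channels[[i]]
  image_stack(vox, names(channels), voxel_size_um)
}

# marker_mask wrapper around a raw logical volume (for feature tests
# that need a mask with known geometry)
mask_from_array <- function(m, role = "TH") {
  stack <- stack_from_channels(setNames(
    list(array(ifelse(m, 1000, 0), dim = dim(m))), role))
  make_marker_mask(stack, role, window_vox = c(1, 1, 1),
                   threshold_method = "fixed", fixed_threshold = 500)
}

# ---- brute-force oracles -------------------------------------------------

# per-voxel median with whole-sample symmetric reflection
oracle_median3d <- function(vol, w) {
  d <- dim(vol)
  refl <- function(i, n) {
    if (n == 1) return(1)
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  r <- (w - 1) %/% 2
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    vals <- c()
    for (oz in -r[1]:r[1]) for (oy in -r[2]:r[2]) for (ox in -r[3]:r[3])
      vals <- c(vals, vol[refl(z + oz, d[1]), refl(y + oy, d[2]),
                          refl(x + ox, d[3])])
    out[z, y, x] <- median(vals)
  }
  out
}

# direct (non-separable) convolution with a truncated sampled Gaussian,
# reflected boundaries
oracle_gauss3d <- function(vol, sigma) {
  d <- dim(vol)
  r <- pmax(1, ceiling(3 * sigma))
  k1 <- function(s, r) {
    w <- exp(-((-r):r)^2 / (2 * s^2))
    w / sum(w)
  }
  wz <- k1(sigma[1], r[1]); wy <- k1(sigma[2], r[2]); wx <- k1(sigma[3], r[3])
  refl <- function(i, n) {
    if (n == 1) return(1)
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    acc <- 0
    for (oz in -r[1]:r[1]) for (oy in -r[2]:r[2]) for (ox in -r[3]:r[3])
      acc <- acc + wz[oz + r[1] + 1] * wy[oy + r[2] + 1] *
        wx[ox + r[3] + 1] *
        vol[refl(z + oz, d[1]), refl(y + oy, d[2]), refl(x + ox, d[3])]
    out[z, y, x] <- acc
  }
  out
}

# erosion: voxel kept iff every structuring-element neighbour (cross for
# 6, cube for 26) is inside the mask and inside the volume
oracle_erode3d <- function(m, connectivity = 6) {
  d <- dim(m)
  out <- array(FALSE, d)
  offs <- expand.grid(oz = -1:1, oy = -1:1, ox = -1:1)
  offs <- offs[!(offs$oz == 0 & offs$oy == 0 & offs$ox == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$oz) + abs(offs$oy) + abs(offs$ox) == 1, ]
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (!m[z, y, x]) next
    keep <- TRUE
    for (i in seq_len(nrow(offs))) {
      p <- c(z + offs$oz[i], y + offs$oy[i], x + offs$ox[i])
      if (any(p < 1) || any(p > d) || !m[p[1], p[2], p[3]]) {
        keep <- FALSE
        break
      }
    }
    out[z, y, x] <- keep
  }
  out
}

# perinuclear zone membership by direct distance computation: voxel
# belongs to the zone of the nucleus with the nearest labelled voxel
# within ring_width (ties to the lower label)
oracle_ring <- function(labels, ring_width) {
  d <- dim(labels)
  fg <- which(labels > 0, arr.ind = TRUE)
  out <- array(0L, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (labels[z, y, x] > 0) next
    dist2 <- (fg[, 1] - z)^2 + (fg[, 2] - y)^2 + (fg[, 3] - x)^2
    dmin <- min(dist2)
    if (dmin <= ring_width^2) {
      cand <- labels[fg[dist2 == dmin, , drop = FALSE]]
      out[z, y, x] <- min(cand)
    }
  }
  out
}

# two-sided exact Mann-Whitney p by enumerating every group assignment
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(a, b)
  nm <- na * length(b)
  combos <- combn(n, na)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  # two-sided: as or more extreme in distance from the null mean nm/2
  mean(abs(us - nm / 2) >= abs(u_obs - nm / 2) - 1e-9)
}

# a one-row feature table with a chosen Hoechst sum
features_row <- function(nuclear_pixels, organoid_id = "o1",
                         line_id = "H", section_index = 1L) {
  data.frame(organoid_id = organoid_id, line_id = line_id,
             section_index = section_index,
             gfap_percentage = 40, s100b_percentage = 20,
             tuj1_pixels = 1000L, th_fragmentation = 0.4,
             nuclear_pixels = nuclear_pixels, n_cells = 20L,
             qc_pass = NA, stringsAsFactors = FALSE)
}

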