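#' Multi-channel 3D image stack
#'
#' The raw input container of the pipeline: a nonnegative intensity array
#' indexed `(z, y, x, channel)` with channel-role labels and the physical
#' voxel size. Physical 50 um vibratome sections imaged as single planes
#' are represented as z-depth-1 stacks so all operations are written once
#' for 3D. All pixel-count features downstream are computed in voxel
#' units; the micrometre spacing is metadata.
#'
#' @param voxels numeric array with `dim = c(nz, ny, nx, n_channels)`;
#'   finite and `>= 0`.
#' @param channel_roles character vector, one entry per channel, each
#'   either one of [CHANNEL_ROLES] or `NA` for an unmapped channel. A role
#'   may appear at most once.
#' @param voxel_size_um physical spacing `(z, y, x)` in micrometres, all
#'   `> 0`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, channel_roles,
                        voxel_size_um = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    stop("`voxels` must be a 4D array (z, y, x, channel)")
  if (!is.numeric(voxels) || anyNA(voxels) || any(!is.finite(voxels)))
    stop("all intensities must be finite")
  if (any(voxels < 0)) stop("all intensities must be >= 0")
  channel_roles <- as.character(channel_roles)
  if (length(channel_roles) != dim(voxels)[4L])
    stop("`channel_roles` must have one entry per channel")
  known <- channel_roles[!is.na(channel_roles)]
  if (!all(known %in% CHANNEL_ROLES))
    stop("unknown channel role(s): ",
         paste(setdiff(known, CHANNEL_ROLES), collapse = ", "))
  if (anyDuplicated(known))
    stop("every channel role may appear at most once")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be three positive numbers (z, y, x)")
  structure(
    list(voxels = voxels, channel_roles = channel_roles,
         voxel_size_um = voxel_size_um),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels (z, y, x), %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  cat("  roles:", paste(ifelse(is.na(x$channel_roles), "<unmapped>",
                               x$channel_roles), collapse = ", "), "\n")
  cat(sprintf("  voxel size (um): z=%g y=%g x=%g\n",
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Test whether a stack carries a channel role
#' @param stack an [image_stack()].
#' @param role a channel role name.
#' @return logical.
#' @export
has_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  role %in% stack$channel_roles
}

#' Extract one channel of a stack as a 3D array
#' @inheritParams has_channel
#' @return numeric array `dim = c(nz, ny, nx)`.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(role, stack$channel_roles)
  if (is.na(i)) stop("channel role '", role, "' absent from stack")
  stack$voxels[, , , i, drop = FALSE] |> drop_channel_dim()
}

# drop only the 4th margin, never z when nz == 1
drop_channel_dim <- function(a) {
  d <- dim(a)
  array(a, dim = d[1:3])
}

#' One organoid section and its image
#'
#' Couples an [image_stack()] with the identifiers used for grouping and
#' quality-control reporting: the organoid it was cut from, the cell line
#' (group) it belongs to, and the section index within the organoid.
#'
#' @param organoid_id,line_id character scalars.
#' @param section_index integer `>= 0`.
#' @param stack an [image_stack()].
#' @return an object of class `section_record`.
#' @export
section_record <- function(organoid_id, line_id, section_index, stack) {
  stopifnot(is.character(organoid_id), length(organoid_id) == 1L,
            is.character(line_id), length(line_id) == 1L,
            inherits(stack, "image_stack"))
  section_index <- as.integer(section_index)
  stopifnot(length(section_index) == 1L, !is.na(section_index),
            section_index >= 0L)
  structure(
    list(organoid_id = organoid_id, line_id = line_id,
         section_index = section_index, stack = stack),
    class = "section_record"
  )
}

#' @export
print.section_record <- function(x, ...) {
  cat(sprintf("<section_record> organoid=%s line=%s section=%d\n",
              x$organoid_id, x$line_id, x$section_index))
  print(x$stack)
  invisible(x)
}

check_unique_sections <- function(records) {
  keys <- vapply(records, function(r)
    paste(r$organoid_id, r$section_index, sep = "\r"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (organoid_id, section_index) in record set")
  invisible(TRUE)
}
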