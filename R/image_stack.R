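#' Calibrated multi-channel image stack
#'
#' Container for a multi-channel fluorescence intensity volume together
#' with its physical calibration and acquisition annotations. The
#' intensity grid is always stored as a 4-dimensional array indexed
#' `(channel, z, y, x)`; 2D images get a singleton z dimension so every
#' downstream operation sees one canonical layout.
#'
#' @param intensities Numeric array indexed `(channel, z, y, x)`, or a
#'   plain `y` by `x` matrix (promoted to a single-channel, single-plane
#'   stack). All values must be finite and non-negative.
#' @param pixel_size_nm Lateral pixel size in nm/pixel (positive).
#' @param channel_labels Character vector of unique channel names, one
#'   per channel (e.g. `"sd-rxRNA-Cy3"`, `"EGF-Alexa488"`). Defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param z_spacing_nm Axial slice spacing in nm. May be `NA` for a
#'   single-plane stack; required (positive) when there is more than one
#'   z slice.
#' @param time_min Acquisition time point in minutes (or `NA`).
#' @param condition Experimental condition label (or `NA`).
#' @param cell_id Cell identifier (or `NA`).
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(intensities, pixel_size_nm, channel_labels = NULL,
                        z_spacing_nm = NA_real_, time_min = NA_real_,
                        condition = NA_character_, cell_id = NA_character_) {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, dim = c(1L, 1L, dim(intensities)))
  }
  if (!is.numeric(intensities) || length(dim(intensities)) != 4L) {
    vc_validation_error(
      "intensities must be a (channel, z, y, x) array or a 2D matrix")
  }
  if (!all(is.finite(intensities))) {
    vc_validation_error("intensities contain non-finite values")
  }
  if (any(intensities < 0)) {
    vc_validation_error("intensities must be non-negative")
  }
  n_ch <- dim(intensities)[1L]
  n_z <- dim(intensities)[2L]
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n_ch))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != n_ch) {
    vc_annotation_error(sprintf(
      "%d channel labels supplied for %d channels", length(channel_labels), n_ch))
  }
  if (anyDuplicated(channel_labels)) {
    vc_annotation_error("channel labels must be unique")
  }
  if (!is_scalar_number(pixel_size_nm) || pixel_size_nm <= 0) {
    vc_calibration_error("pixel_size_nm must be a positive number")
  }
  z_spacing_nm <- as.numeric(z_spacing_nm)
  if (!is.na(z_spacing_nm) && z_spacing_nm <= 0) {
    vc_calibration_error("z_spacing_nm must be positive when given")
  }
  if (n_z > 1L && is.na(z_spacing_nm)) {
    vc_calibration_error("z_spacing_nm is required for stacks with more than one z slice")
  }
  structure(list(
    intensities = intensities,
    pixel_size_nm = as.numeric(pixel_size_nm),
    z_spacing_nm = z_spacing_nm,
    channel_labels = channel_labels,
    time_min = as.numeric(time_min),
    condition = as.character(condition),
    cell_id = as.character(cell_id)
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("image_stack: %d channel(s) [%s], %d z, %d x %d px\n",
              d[1], paste(x$channel_labels, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  pixel size %g nm, z spacing %s nm\n", x$pixel_size_nm,
              ifelse(is.na(x$z_spacing_nm), "-", format(x$z_spacing_nm))))
  cat(sprintf("  time %s min, condition %s, cell %s\n",
              format(x$time_min), x$condition, x$cell_id))
  invisible(x)
}

#' Number of channels / z slices in a stack
#' @param stack An `image_stack`.
#' @return Integer count.
#' @export
n_channels <- function(stack) dim(stack$intensities)[1L]

#' @rdname n_channels
#' @export
n_slices <- function(stack) dim(stack$intensities)[2L]

channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    i <- as.integer(channel)
    if (i < 1L || i > n_channels(stack)) {
      vc_annotation_error(sprintf("channel index %d out of range", i))
    }
    return(i)
  }
  i <- match(channel, stack$channel_labels)
  if (is.na(i)) {
    vc_annotation_error(sprintf(
      "channel '%s' not present (have: %s)", channel,
      paste(stack$channel_labels, collapse = ", ")))
  }
  i
}

#' Extract one channel as a (z, y, x) array
#' @param stack An `image_stack`.
#' @param channel Channel label or index.
#' @return Numeric array of dimension `(n_z, n_y, n_x)`.
#' @export
get_channel <- function(stack, channel) {
  i <- channel_index(stack, channel)
  v <- stack$intensities[i, , , , drop = FALSE]
  array(v, dim = dim(stack$intensities)[-1L])
}

#' Extract a single 2D plane of one channel
#' @inheritParams get_channel
#' @param z Z-slice index (default 1).
#' @return Numeric `y` by `x` matrix.
#' @export
channel_plane <- function(stack, channel, z = 1L) {
  a <- get_channel(stack, channel)
  if (z < 1L || z > dim(a)[1L]) vc_geometry_error("z index out of range")
  matrix(a[z, , ], nrow = dim(a)[2L], ncol = dim(a)[3L])
}
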