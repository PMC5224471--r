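#' Total fluorescence intensity of a channel
#'
#' Sums the channel's intensities over the whole stack or over an
#' optional region mask (a 2D `y` by `x` mask is applied to every z
#' slice).
#'
#' @param stack An [image_stack()].
#' @param channel Channel label or index.
#' @param region Optional [binary_mask()] or 0/1 (or logical) matrix.
#' @return Non-negative scalar.
#' @export
total_intensity <- function(stack, channel, region = NULL) {
  arr <- get_channel(stack, channel)
  if (is.null(region)) return(sum(arr))
  reg <- region
  if (inherits(reg, "binary_mask")) reg <- reg$values
  reg <- reg > 0
  if (!identical(dim(reg), dim(arr)[2:3])) {
    vc_geometry_error("region mask must match the (y, x) image shape")
  }
  if (!any(reg)) vc_degenerate_error("region mask is empty")
  sum(vapply(seq_len(dim(arr)[1L]), function(z) {
    m <- matrix(arr[z, , ], nrow = dim(arr)[2L], ncol = dim(arr)[3L])
    sum(m[reg])
  }, numeric(1)))
}

# sample a plane at continuous (y, x) positions (1-based pixel centres)
interp_plane <- function(plane, y, x, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  ny <- nrow(plane); nx <- ncol(plane)
  eps <- 1e-9
  if (any(y < 1 - eps | y > ny + eps | x < 1 - eps | x > nx + eps)) {
    vc_geometry_error("sample point falls outside the image")
  }
  y <- pmin(pmax(y, 1), ny); x <- pmin(pmax(x, 1), nx)
  if (method == "nearest") {
    return(plane[cbind(round(y), round(x))])
  }
  y0 <- pmin(pmax(floor(y), 1L), ny - 1L)
  x0 <- pmin(pmax(floor(x), 1L), nx - 1L)
  fy <- y - y0; fx <- x - x0
  (1 - fy) * (1 - fx) * plane[cbind(y0, x0)] +
    (1 - fy) * fx * plane[cbind(y0, x0 + 1L)] +
    fy * (1 - fx) * plane[cbind(y0 + 1L, x0)] +
    fy * fx * plane[cbind(y0 + 1L, x0 + 1L)]
}

#' Perinuclear line-profile readout
#'
#' Samples a 2D plane along a user-supplied line (drawn through the
#' longest part of the cell, crossing the nucleus) at 1-pixel steps,
#' locates the contiguous interval of the line inside the nucleus
#' mask, and reads the intensity at a fixed distance (default 10
#' pixels, measured along the line in native pixels) outside each
#' nucleus-boundary crossing. The full plot profile is returned
#' alongside the two flank values.
#'
#' @param plane Numeric `y` by `x` matrix (the cargo channel).
#' @param nucleus_mask [binary_mask()] or 0/1 matrix of the nucleus
#'   (e.g. an Otsu-thresholded DAPI channel), same shape as `plane`.
#' @param endpoints 2 x 2 numeric matrix; rows are the `(y, x)` line
#'   endpoints in pixel coordinates.
#' @param flank_px Distance beyond the nucleus boundary, pixels.
#' @param interpolation `"bilinear"` (default) or `"nearest"` (exact
#'   on integer fixtures).
#' @return An object of class `line_profile` with fields `endpoints`,
#'   `samples` (data.frame of `position_px`, `intensity`),
#'   `nucleus_interval`, `flank_positions`, `flank_values`.
#' @export
perinuclear_readout <- function(plane, nucleus_mask, endpoints,
                                flank_px = 10,
                                interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  endpoints <- matrix(as.numeric(endpoints), nrow = 2L)
  nuc <- if (inherits(nucleus_mask, "binary_mask")) nucleus_mask$values else nucleus_mask
  check_same_shape(plane, nuc)
  p0 <- endpoints[1L, ]; p1 <- endpoints[2L, ]
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) vc_geometry_error("line endpoints coincide")
  s <- seq(0, len, by = 1)
  if (s[length(s)] < len) s <- c(s, len)
  dir_u <- (p1 - p0) / len
  at <- function(pos) cbind(p0[1L] + pos * dir_u[1L], p0[2L] + pos * dir_u[2L])
  pts <- at(s)
  vals <- interp_plane(plane, pts[, 1L], pts[, 2L], interpolation)
  inside <- interp_plane(nuc, pts[, 1L], pts[, 2L], "nearest") > 0.5
  idx <- which(inside)
  if (!length(idx)) vc_geometry_error("line does not cross the nucleus")
  if (length(idx) == length(s)) {
    vc_geometry_error("nucleus mask covers the entire line")
  }
  if (any(diff(idx) != 1L)) {
    vc_geometry_error("line crosses the nucleus in more than one interval")
  }
  s_in <- c(s[min(idx)], s[max(idx)])
  f_pos <- c(s_in[1L] - flank_px, s_in[2L] + flank_px)
  if (f_pos[1L] < 0 || f_pos[2L] > len) {
    vc_geometry_error("flank point falls outside the line/image")
  }
  f_pts <- at(f_pos)
  f_vals <- interp_plane(plane, f_pts[, 1L], f_pts[, 2L], interpolation)
  structure(list(
    endpoints = endpoints,
    samples = data.frame(position_px = s, intensity = vals),
    nucleus_interval = s_in,
    flank_positions = f_pos,
    flank_values = c(left = f_vals[1L], right = f_vals[2L])
  ), class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf(
    "line_profile: %d samples, nucleus at [%.1f, %.1f] px, flanks %.4g / %.4g\n",
    nrow(x$samples), x$nucleus_interval[1L], x$nucleus_interval[2L],
    x$flank_values[1L], x$flank_values[2L]))
  invisible(x)
}
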