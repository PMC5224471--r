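#' Difference-of-Gaussians detector parameters
#'
#' The vesicle detector subtracts a wide Gaussian local-background
#' estimate from a narrow, near-diffraction-limited spot matched
#' filter. Defaults are a 150 nm sigma detector and a 300 nm sigma
#' background estimator; both are specified physically (nm) and
#' converted to pixels using the image calibration.
#'
#' @param sigma_small_nm Sigma of the spot-matched Gaussian, nm.
#' @param sigma_large_nm Sigma of the background Gaussian, nm; must
#'   exceed `sigma_small_nm` for a meaningful band-pass.
#' @param truncation_sigmas Kernel half-width in units of
#'   `sigma_large_nm` (default 4).
#' @return An object of class `dog_params`.
#' @export
dog_params <- function(sigma_small_nm = 150, sigma_large_nm = 300,
                       truncation_sigmas = 4) {
  for (v in c(sigma_small_nm, sigma_large_nm, truncation_sigmas)) {
    if (!is_scalar_number(v) || v <= 0) {
      vc_parameter_error("dog_params fields must be positive numbers")
    }
  }
  if (sigma_small_nm >= sigma_large_nm) {
    vc_parameter_error("sigma_small_nm must be smaller than sigma_large_nm")
  }
  structure(list(sigma_small_nm = sigma_small_nm,
                 sigma_large_nm = sigma_large_nm,
                 truncation_sigmas = truncation_sigmas),
            class = "dog_params")
}

# discrete 2D Gaussian on a (2r+1)^2 grid, renormalized to sum to 1 so
# that "unit area" holds exactly after truncation
discrete_gaussian2d <- function(sigma_px, radius) {
  x <- seq(-radius, radius)
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma_px^2))
  g / sum(g)
}

#' Build the discrete DOG kernel
#'
#' `kernel = G_small - G_large`, where each truncated discrete Gaussian
#' is renormalized to sum exactly to 1 (unit area minus negative unit
#' area), so the kernel sums to zero to machine precision and a flat
#' image yields a zero response.
#'
#' @param params A [dog_params()].
#' @param pixel_size_nm Lateral pixel size, nm.
#' @param check If `TRUE` (default), reject `sigma_small_nm >=
#'   sigma_large_nm`; `check = FALSE` permits degenerate sigmas (equal
#'   sigmas give the all-zero kernel).
#' @return Square numeric matrix with attribute `radius` (pixels).
#' @export
build_dog_kernel <- function(params, pixel_size_nm, check = TRUE) {
  if (!is_scalar_number(pixel_size_nm) || pixel_size_nm <= 0) {
    vc_parameter_error("pixel_size_nm must be positive")
  }
  if (check && params$sigma_small_nm >= params$sigma_large_nm) {
    vc_parameter_error("sigma_small_nm must be smaller than sigma_large_nm")
  }
  radius <- as.integer(ceiling(
    params$truncation_sigmas * params$sigma_large_nm / pixel_size_nm))
  k <- discrete_gaussian2d(params$sigma_small_nm / pixel_size_nm, radius) -
       discrete_gaussian2d(params$sigma_large_nm / pixel_size_nm, radius)
  attr(k, "radius") <- radius
  attr(k, "pixel_size_nm") <- pixel_size_nm
  k
}

# symmetric reflection padding (edge pixel duplicated), r on every side
reflect_pad <- function(m, r) {
  ny <- nrow(m); nx <- ncol(m)
  if (r >= ny || r >= nx) {
    vc_validation_error(sprintf(
      "plane (%d x %d) smaller than kernel radius %d; cannot reflect-pad",
      ny, nx, r))
  }
  iy <- c(rev(seq_len(r)), seq_len(ny), ny - seq_len(r) + 1L)
  ix <- c(rev(seq_len(r)), seq_len(nx), nx - seq_len(r) + 1L)
  m[iy, ix]
}

#' Apply the DOG vesicle filter to a 2D plane
#'
#' Convolves the plane with the zero-sum DOG kernel. Boundaries are
#' handled by reflection padding so that flat regions at the image edge
#' do not produce spurious puncta. Filtering is strictly 2D, applied
#' per plane or per projected slab.
#'
#' @param plane Numeric matrix (finite values).
#' @param params A [dog_params()].
#' @param pixel_size_nm Lateral pixel size, nm.
#' @return Numeric matrix of the same shape as `plane`.
#' @export
dog_filter <- function(plane, params = dog_params(), pixel_size_nm) {
  if (!is.matrix(plane) || !is.numeric(plane)) {
    vc_validation_error("plane must be a numeric matrix")
  }
  if (!all(is.finite(plane))) {
    vc_validation_error("plane contains non-finite values")
  }
  k <- build_dog_kernel(params, pixel_size_nm)
  r <- attr(k, "radius")
  padded <- reflect_pad(plane, r)
  out <- EBImage::filter2(padded, k, boundary = "circular")
  out <- out[(r + 1L):(r + nrow(plane)), (r + 1L):(r + ncol(plane)),
             drop = FALSE]
  matrix(as.numeric(out), nrow = nrow(plane), ncol = ncol(plane))
}

#' Binary detection mask
#'
#' @param values Matrix (or array) of 0/1 values.
#' @param label Channel label the mask was derived from.
#' @param threshold_used The global threshold that produced the mask
#'   (recorded for provenance).
#' @param time_min Acquisition time of the source image, minutes.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, label = NA_character_,
                        threshold_used = NA_real_, time_min = NA_real_) {
  if (!is.numeric(values) || !all(values %in% c(0, 1))) {
    vc_validation_error("binary mask values must be 0 or 1")
  }
  structure(list(values = values, label = as.character(label),
                 threshold_used = as.numeric(threshold_used),
                 time_min = as.numeric(time_min)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask '%s': %d / %d on-pixels (%.3g%%), threshold %g\n",
              x$label, sum(x$values), length(x$values),
              100 * mean(x$values), x$threshold_used))
  invisible(x)
}

# accept binary_mask objects or raw 0/1 matrices interchangeably
mask_values <- function(m) {
  v <- if (inherits(m, "binary_mask")) m$values else m
  if (!is.numeric(v) || !all(v %in% c(0, 1))) {
    vc_validation_error("mask values must be 0 or 1")
  }
  v
}

mask_label <- function(m, default = NA_character_) {
  if (inherits(m, "binary_mask") && !is.na(m$label)) m$label else default
}

#' Threshold a filtered image into a binary mask
#'
#' Sets every pixel strictly above the global threshold to 1 and all
#' others to 0, recording the threshold on the mask.
#'
#' @param filtered Numeric matrix (typically DOG-filtered).
#' @param threshold Finite scalar threshold.
#' @param label,time_min Provenance carried onto the mask.
#' @return A [binary_mask()].
#' @export
global_threshold <- function(filtered, threshold, label = NA_character_,
                             time_min = NA_real_) {
  if (!is_scalar_number(threshold) || !is.finite(threshold)) {
    vc_validation_error("threshold must be a finite number")
  }
  binary_mask((filtered > threshold) * 1L, label = label,
              threshold_used = threshold, time_min = time_min)
}

#' Automatic global threshold for a filtered image
#'
#' The original procedure thresholded by eye, which is not
#' reproducible; the default here applies Otsu's criterion to the
#' strictly positive filtered values only (`"otsu-positive"`): after
#' zero-sum DOG filtering, background fluctuates around zero, so the
#' positive tail is a mixture of noise and spot responses that Otsu
#' separates. A plain quantile rule is available as an alternative.
#'
#' @param filtered Numeric matrix of filtered values.
#' @param method `"otsu-positive"` or `"quantile"`.
#' @param q Quantile in `[0, 1]` (required for `method = "quantile"`).
#' @param n_bins Histogram bins for the Otsu scan.
#' @return Scalar threshold.
#' @export
auto_threshold <- function(filtered, method = c("otsu-positive", "quantile"),
                           q = NULL, n_bins = 256L) {
  method <- match.arg(method)
  if (method == "quantile") {
    if (is.null(q) || !is_scalar_number(q) || q < 0 || q > 1) {
      vc_parameter_error("method 'quantile' needs q in [0, 1]")
    }
    return(unname(stats::quantile(filtered, probs = q, names = FALSE)))
  }
  v <- filtered[filtered > 0]
  if (!length(v)) {
    vc_degenerate_error("no positive filtered values; cannot apply Otsu")
  }
  vmax <- max(v)
  if (min(v) == vmax) return(vmax / 2)
  breaks <- seq(0, vmax, length.out = n_bins + 1L)
  cnt <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                       n_bins), nbins = n_bins)
  p <- cnt / sum(cnt)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mt <- mu0[n_bins]
  valid <- w0 > 0 & w0 < 1
  sb <- rep(-Inf, n_bins)
  sb[valid] <- (mt * w0[valid] - mu0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(sb)
  breaks[k + 1L]  # upper edge of the background class
}
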