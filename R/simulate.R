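#' Peak amplitude needed for a target peak signal-to-noise ratio
#'
#' With Poisson shot noise on the expected counts plus Gaussian read
#' noise, the noise at a punctum peak is
#' `sqrt(amplitude + background + read_sigma^2)`, so the amplitude
#' giving peak SNR `s` solves `A = s * sqrt(A + b + r^2)`.
#'
#' @param snr Target peak signal-to-noise ratio.
#' @param background Expected background level (counts).
#' @param read_sigma Read-noise standard deviation (counts).
#' @return Peak amplitude in counts.
#' @export
amplitude_for_snr <- function(snr, background, read_sigma) {
  (snr^2 + sqrt(snr^4 + 4 * snr^2 * (background + read_sigma^2))) / 2
}

#' Synthetic scene specification
#'
#' Parameters of a simulated multi-channel fluorescence stack with
#' known ground truth. Defaults emulate the imaging regime the
#' pipeline is built for: a 512 x 512 field at 100 nm/pixel,
#' diffraction-limited puncta (Gaussian PSF, sigma 130 nm) over a
#' constant offset plus a diffuse membrane-like field, Poisson shot
#' noise and Gaussian read noise at peak SNR ~10, and 50 puncta per
#' channel with a minimum within-channel separation of 5 PSF sigmas so
#' that scenes with `coloc_fraction = 0` contain no accidental
#' overlaps by construction.
#'
#' @param n_y,n_x,n_z Grid shape (z defaults to a single plane).
#' @param pixel_size_nm,z_spacing_nm Calibration, nm.
#' @param channel_labels Channel names (2 or more).
#' @param n_puncta Puncta per channel (recycled).
#' @param psf_sigma_nm PSF Gaussian sigma, nm.
#' @param amplitude Peak amplitude in counts; if `NULL`, derived from
#'   `snr` via [amplitude_for_snr()].
#' @param snr Target peak signal-to-noise ratio (used when `amplitude`
#'   is `NULL`).
#' @param coloc_fraction Fraction of the second channel's puncta that
#'   share positions with puncta of the first channel, in `[0, 1]`.
#' @param coloc_channels Indices of the designated channel pair.
#' @param jitter_nm Maximum positional offset applied to co-located
#'   partners (models imperfect registration; 0 = exact sharing).
#' @param background_offset Constant background, counts.
#' @param membrane_amplitude Peak of the broad Gaussian membrane-like
#'   field added to every slice, counts.
#' @param poisson Apply Poisson shot noise?
#' @param read_sigma Gaussian read-noise sd, counts (0 disables).
#' @param min_sep_factor Minimum within-channel punctum separation, in
#'   PSF sigmas.
#' @param seed Integer; fully determines the scene.
#' @param time_min,condition,cell_id Annotations forwarded to the
#'   generated stack.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_y = 512L, n_x = 512L, n_z = 1L,
                       pixel_size_nm = 100, z_spacing_nm = 100,
                       channel_labels = c("cargo", "marker"),
                       n_puncta = 50L, psf_sigma_nm = 130,
                       amplitude = NULL, snr = 10,
                       coloc_fraction = 0, coloc_channels = c(1L, 2L),
                       jitter_nm = 0, background_offset = 10,
                       membrane_amplitude = 5,
                       poisson = TRUE, read_sigma = 2,
                       min_sep_factor = 5, seed = 1L,
                       time_min = NA_real_, condition = NA_character_,
                       cell_id = NA_character_) {
  if (!is_scalar_number(coloc_fraction) || coloc_fraction < 0 ||
      coloc_fraction > 1) {
    vc_parameter_error("coloc_fraction must lie in [0, 1]")
  }
  n_ch <- length(channel_labels)
  if (n_ch < 2L) vc_parameter_error("at least two channels are required")
  n_puncta <- rep_len(as.integer(n_puncta), n_ch)
  if (is.null(amplitude)) {
    amplitude <- amplitude_for_snr(snr, background_offset, read_sigma)
  }
  amplitude <- rep_len(as.numeric(amplitude), n_ch)
  structure(list(
    n_y = as.integer(n_y), n_x = as.integer(n_x), n_z = as.integer(n_z),
    pixel_size_nm = pixel_size_nm, z_spacing_nm = z_spacing_nm,
    channel_labels = channel_labels, n_puncta = n_puncta,
    psf_sigma_nm = psf_sigma_nm, amplitude = amplitude,
    coloc_fraction = coloc_fraction,
    coloc_channels = as.integer(coloc_channels),
    jitter_nm = jitter_nm, background_offset = background_offset,
    membrane_amplitude = membrane_amplitude,
    poisson = isTRUE(poisson), read_sigma = read_sigma,
    min_sep_factor = min_sep_factor, seed = as.integer(seed),
    time_min = time_min, condition = condition, cell_id = cell_id
  ), class = "scene_spec")
}

# rejection-sample n centres (px units) with a minimum mutual distance,
# optionally keeping distance from pre-existing centres of the same
# channel
sample_centers <- function(n, n_y, n_x, margin, min_sep_px, existing = NULL) {
  ys <- numeric(0); xs <- numeric(0)
  if (!is.null(existing)) { ys <- existing[, 1L]; xs <- existing[, 2L] }
  n_kept <- length(ys)
  out_y <- numeric(n); out_x <- numeric(n)
  tries <- 0L; max_tries <- 1000L * max(n, 1L)
  k <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      vc_parameter_error(
        "cannot place puncta at the requested density and minimum separation")
    }
    cy <- runif(1, margin, n_y + 1 - margin)
    cx <- runif(1, margin, n_x + 1 - margin)
    if (length(ys) &&
        min((ys - cy)^2 + (xs - cx)^2) < min_sep_px^2) next
    k <- k + 1L
    out_y[k] <- cy; out_x[k] <- cx
    ys <- c(ys, cy); xs <- c(xs, cx)
  }
  cbind(y = out_y, x = out_x)
}

# add one Gaussian spot (peak `amp`, sigma in px, subpixel centre) to a
# matrix in place-ish
add_spot <- function(m, cy, cx, sigma_px, amp) {
  win <- ceiling(4 * sigma_px)
  ys <- max(1L, floor(cy) - win):min(nrow(m), floor(cy) + win)
  xs <- max(1L, floor(cx) - win):min(ncol(m), floor(cx) + win)
  patch <- amp * exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * sigma_px^2))
  m[ys, xs] <- m[ys, xs] + patch
  m
}

#' Simulate one synthetic scene
#'
#' Renders each punctum as an isotropic 2D Gaussian (the PSF) on its z
#' slice at a uniform-random position; a designated fraction of the
#' second paired channel's puncta share positions with the first
#' channel's (up to `jitter_nm`). A constant offset and a broad
#' membrane-like Gaussian field are added, then Poisson shot noise and
#' Gaussian read noise (clamped at zero). The same spec (including
#' seed) always yields a bit-identical stack.
#'
#' @param spec A [scene_spec()].
#' @return List of class `synthetic_scene` with elements `stack` (an
#'   [image_stack()]), `truth` (ground truth: per-channel punctum
#'   tables, co-located pair indices, per-channel expected intensity
#'   totals) and `spec`.
#' @export
simulate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) vc_parameter_error("spec must be a scene_spec")
  set.seed(spec$seed)
  n_ch <- length(spec$channel_labels)
  sigma_px <- spec$psf_sigma_nm / spec$pixel_size_nm
  margin <- ceiling(4 * sigma_px) + 1
  min_sep_px <- spec$min_sep_factor * sigma_px
  ci <- spec$coloc_channels[1L]; cj <- spec$coloc_channels[2L]

  centers <- vector("list", n_ch)
  zidx <- vector("list", n_ch)
  coloc_flag <- vector("list", n_ch)

  # paired reference channel first
  centers[[ci]] <- sample_centers(spec$n_puncta[ci], spec$n_y, spec$n_x,
                                  margin, min_sep_px)
  zidx[[ci]] <- sample.int(spec$n_z, spec$n_puncta[ci], replace = TRUE)
  coloc_flag[[ci]] <- rep(FALSE, spec$n_puncta[ci])

  # partner channel: shared subset + independent rest
  n_j <- spec$n_puncta[cj]
  n_shared <- round(spec$coloc_fraction * n_j)
  n_shared <- min(n_shared, spec$n_puncta[ci])
  shared_idx <- if (n_shared > 0) {
    sort(sample.int(spec$n_puncta[ci], n_shared))
  } else integer(0)
  shared <- centers[[ci]][shared_idx, , drop = FALSE]
  if (n_shared > 0 && spec$jitter_nm > 0) {
    ang <- runif(n_shared, 0, 2 * pi)
    rad <- runif(n_shared, 0, spec$jitter_nm) / spec$pixel_size_nm
    shared[, 1L] <- shared[, 1L] + rad * sin(ang)
    shared[, 2L] <- shared[, 2L] + rad * cos(ang)
  }
  indep <- sample_centers(n_j - n_shared, spec$n_y, spec$n_x, margin,
                          min_sep_px, existing = shared)
  centers[[cj]] <- rbind(shared, indep)
  zidx[[cj]] <- c(zidx[[ci]][shared_idx],
                  sample.int(spec$n_z, n_j - n_shared, replace = TRUE))
  coloc_flag[[cj]] <- c(rep(TRUE, n_shared), rep(FALSE, n_j - n_shared))
  coloc_flag[[ci]][shared_idx] <- TRUE

  # remaining channels are independent
  for (ch in setdiff(seq_len(n_ch), c(ci, cj))) {
    centers[[ch]] <- sample_centers(spec$n_puncta[ch], spec$n_y, spec$n_x,
                                    margin, min_sep_px)
    zidx[[ch]] <- sample.int(spec$n_z, spec$n_puncta[ch], replace = TRUE)
    coloc_flag[[ch]] <- rep(FALSE, spec$n_puncta[ch])
  }

  yy <- seq_len(spec$n_y); xx <- seq_len(spec$n_x)
  sig_mb <- 0.35 * min(spec$n_y, spec$n_x)
  bg <- spec$background_offset + spec$membrane_amplitude *
    exp(-outer((yy - (spec$n_y + 1) / 2)^2,
               (xx - (spec$n_x + 1) / 2)^2, "+") / (2 * sig_mb^2))

  arr <- array(0, dim = c(n_ch, spec$n_z, spec$n_y, spec$n_x))
  totals <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    expected <- array(0, dim = c(spec$n_z, spec$n_y, spec$n_x))
    for (z in seq_len(spec$n_z)) {
      plane <- matrix(0, spec$n_y, spec$n_x)
      on_z <- which(zidx[[ch]] == z)
      for (p in on_z) {
        plane <- add_spot(plane, centers[[ch]][p, 1L], centers[[ch]][p, 2L],
                          sigma_px, spec$amplitude[ch])
      }
      expected[z, , ] <- plane
    }
    signal_sum <- sum(expected)
    expected <- expected + rep(bg, each = spec$n_z)
    noisy <- if (spec$poisson) {
      p <- rpois(length(expected), lambda = expected)
      dim(p) <- dim(expected)
      p
    } else expected
    if (spec$read_sigma > 0) {
      noisy <- noisy + rnorm(length(noisy), 0, spec$read_sigma)
    }
    arr[ch, , , ] <- pmax(noisy, 0)
    totals[[ch]] <- list(signal_sum = signal_sum,
                         background_sum = sum(bg) * spec$n_z,
                         total_expected = signal_sum + sum(bg) * spec$n_z)
  }
  names(totals) <- spec$channel_labels

  truth_tabs <- lapply(seq_len(n_ch), function(ch) {
    data.frame(
      channel = spec$channel_labels[ch],
      id = seq_len(nrow(centers[[ch]])),
      y_px = centers[[ch]][, 1L], x_px = centers[[ch]][, 2L],
      y_nm = centers[[ch]][, 1L] * spec$pixel_size_nm,
      x_nm = centers[[ch]][, 2L] * spec$pixel_size_nm,
      z_index = zidx[[ch]],
      colocated = coloc_flag[[ch]],
      stringsAsFactors = FALSE)
  })
  names(truth_tabs) <- spec$channel_labels

  stack <- image_stack(arr, pixel_size_nm = spec$pixel_size_nm,
                       channel_labels = spec$channel_labels,
                       z_spacing_nm = if (spec$n_z > 1L) spec$z_spacing_nm else NA_real_,
                       time_min = spec$time_min, condition = spec$condition,
                       cell_id = spec$cell_id)
  structure(list(
    stack = stack,
    truth = list(puncta = truth_tabs,
                 coloc_pairs = data.frame(
                   index_ref = shared_idx,
                   index_partner = seq_len(n_shared)),
                 totals = totals),
    spec = spec
  ), class = "synthetic_scene")
}

#' Deterministic battery of scenes across co-location fractions
#'
#' Generates `length(fractions) * n_reps` scene specifications from a
#' base spec, each with its own seed derived reproducibly from the
#' master seed, and (optionally) simulates them. Used by the recovery
#' and null-calibration suites.
#'
#' @param fractions Co-location fractions to span.
#' @param n_reps Replicates per fraction (>= 1).
#' @param base_spec A [scene_spec()] supplying all other parameters.
#' @param seed Master seed.
#' @param simulate If `FALSE`, return specs only (callers can then
#'   simulate scenes one at a time to bound memory).
#' @return List of elements `list(spec, scene)` (scene `NULL` when
#'   `simulate = FALSE`).
#' @export
scene_battery <- function(fractions, n_reps, base_spec = scene_spec(),
                          seed = 1L, simulate = TRUE) {
  if (!length(fractions)) vc_parameter_error("fractions must be non-empty")
  if (n_reps < 1L) vc_parameter_error("n_reps must be >= 1")
  set.seed(seed)
  n <- length(fractions) * n_reps
  seeds <- sample.int(.Machine$integer.max, n)
  out <- vector("list", n)
  k <- 1L
  for (i in seq_along(fractions)) {
    for (r in seq_len(n_reps)) {
      spec <- base_spec
      spec$coloc_fraction <- fractions[i]
      spec$seed <- seeds[k]
      spec$cell_id <- sprintf("scene_f%04.0f_r%02d", 1000 * fractions[i], r)
      out[[k]] <- list(spec = spec,
                       scene = if (simulate) simulate_scene(spec) else NULL)
      k <- k + 1L
    }
  }
  out
}

#' Centroids of mask connected components
#'
#' @param mask [binary_mask()] or 0/1 matrix.
#' @return Two-column matrix `(y, x)` of component centroids (0 rows if
#'   the mask is empty).
#' @export
mask_centroids <- function(mask) {
  v <- mask_values(mask)
  lab <- EBImage::bwlabel(v)
  lab <- matrix(as.integer(lab), nrow = nrow(v))
  n <- max(lab)
  if (n == 0L) return(matrix(numeric(0), ncol = 2,
                             dimnames = list(NULL, c("y", "x"))))
  on <- lab > 0
  ys <- tapply(row(lab)[on], lab[on], mean)
  xs <- tapply(col(lab)[on], lab[on], mean)
  cbind(y = as.numeric(ys), x = as.numeric(xs))
}

#' Object-level co-localization fraction
#'
#' Fraction of B's detected objects (mask connected components) whose
#' centroid lies within `radius_px` of some A-object centroid. This is
#' a validation readout for synthetic scenes, not the headline
#' pixel-overlap statistic.
#'
#' @param mask_A,mask_B Masks of identical shape.
#' @param radius_px Matching radius, pixels.
#' @return Fraction in `[0, 1]`, or `NA` if B has no objects.
#' @export
object_coloc_fraction <- function(mask_A, mask_B, radius_px = 2) {
  ca <- mask_centroids(mask_A); cb <- mask_centroids(mask_B)
  if (nrow(cb) == 0L) return(NA_real_)
  if (nrow(ca) == 0L) return(0)
  matched <- vapply(seq_len(nrow(cb)), function(i) {
    min((ca[, 1L] - cb[i, 1L])^2 + (ca[, 2L] - cb[i, 2L])^2) <= radius_px^2
  }, logical(1))
  mean(matched)
}

#' Detection recall and spurious rate against known punctum centres
#'
#' @param mask Detection mask.
#' @param centers_px Two-column `(y, x)` matrix of true centres in
#'   pixel coordinates.
#' @param radius_px Matching radius, pixels.
#' @return List with `recall` (fraction of true centres having a mask
#'   component centroid within radius) and `spurious` (fraction of
#'   components matching no true centre).
#' @export
detection_stats <- function(mask, centers_px, radius_px = 2) {
  cc <- mask_centroids(mask)
  if (nrow(centers_px) == 0L) {
    return(list(recall = NA_real_, spurious = if (nrow(cc)) 1 else 0))
  }
  if (nrow(cc) == 0L) return(list(recall = 0, spurious = 0))
  d2 <- outer(cc[, 1L], centers_px[, 1L], "-")^2 +
        outer(cc[, 2L], centers_px[, 2L], "-")^2
  list(recall = mean(apply(d2, 2L, min) <= radius_px^2),
       spurious = mean(apply(d2, 1L, min) > radius_px^2))
}

#' Write a scene's ground truth as a sidecar CSV
#'
#' @param scene A `synthetic_scene`.
#' @param path Destination CSV.
#' @return The path, invisibly.
#' @export
save_ground_truth <- function(scene, path) {
  df <- do.call(rbind, scene$truth$puncta)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
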