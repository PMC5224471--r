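#' Co-localization result
#'
#' Holds the pixel counts and percentages of a binary-overlap
#' co-localization measurement. The percentage is asymmetric: "B with
#' A" is `100 * sum(A * B) / sum(B)`, the fraction of B's detected
#' pixels that also carry A; "A with B" normalizes by `sum(A)`. The
#' numerator is symmetric under swapping the masks, the percentage
#' generally is not. A zero denominator yields an undefined (`NA`)
#' percentage with `defined = FALSE`; it is never coerced to 0, so an
#' empty channel cannot masquerade as "no co-localization".
#'
#' @param ... Fields, see Details in the package vignette.
#' @return An object of class `coloc_result`.
#' @keywords internal
new_coloc_result <- function(...) {
  structure(list(...), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result [%s]: %s with %s = %s%% (%d / %d px)\n",
              x$direction, x$label_B, x$label_A,
              ifelse(is.na(x$percent), "undefined", sprintf("%.3f", x$percent)),
              x$numerator_px, x$denominator_px))
  if (!is.na(x$null_percent)) {
    cat(sprintf("  180-degree rotation null: %.3f%%\n", x$null_percent))
  }
  if (!is.null(x$per_slab)) {
    cat(sprintf("  pooled over %d slab(s)%s\n", nrow(x$per_slab),
                if (any(x$per_slab$partial)) " (incl. one partial)" else ""))
  }
  invisible(x)
}

check_same_shape <- function(A, B) {
  if (!identical(dim(A), dim(B))) {
    vc_geometry_error("masks must share the same shape")
  }
}

#' Two-way pixel-overlap co-localization percentage
#'
#' Computes `100 * sum(A * B) / sum(B)` for direction `"B_with_A"`
#' (the fraction of B's on-pixels overlapping A) or `100 * sum(A * B)
#' / sum(A)` for `"A_with_B"`. Both directions are stored on the
#' result regardless of which one is requested.
#'
#' @param mask_A,mask_B [binary_mask()] objects (or raw 0/1 matrices)
#'   of identical shape.
#' @param direction `"B_with_A"` (default, normalize by `sum(B)`) or
#'   `"A_with_B"`.
#' @param time_min,cell_id Optional provenance for the result.
#' @return A `coloc_result`.
#' @export
coloc_percent <- function(mask_A, mask_B,
                          direction = c("B_with_A", "A_with_B"),
                          time_min = NA_real_, cell_id = NA_character_) {
  direction <- match.arg(direction)
  A <- mask_values(mask_A); B <- mask_values(mask_B)
  check_same_shape(A, B)
  num <- sum(A * B)
  den_A <- sum(A); den_B <- sum(B)
  den <- if (direction == "B_with_A") den_B else den_A
  pct <- function(n, d) if (d > 0) 100 * n / d else NA_real_
  if (is.na(time_min) && inherits(mask_A, "binary_mask")) {
    time_min <- mask_A$time_min
  }
  new_coloc_result(
    label_A = mask_label(mask_A, "A"), label_B = mask_label(mask_B, "B"),
    direction = direction,
    numerator_px = num, denominator_px = den,
    percent = pct(num, den), defined = den > 0,
    percent_B_with_A = pct(num, den_B), percent_A_with_B = pct(num, den_A),
    null_percent = NA_real_, per_slab = NULL,
    threshold_A = if (inherits(mask_A, "binary_mask")) mask_A$threshold_used else NA_real_,
    threshold_B = if (inherits(mask_B, "binary_mask")) mask_B$threshold_used else NA_real_,
    time_min = time_min, cell_id = cell_id)
}

#' Three-way pixel-overlap co-localization percentage
#'
#' `100 * sum(A * B * C) / sum(normalizer mask)`.
#'
#' @param mask_A,mask_B,mask_C Masks of identical shape.
#' @param normalizer Which mask supplies the denominator: `"A"`, `"B"`,
#'   `"C"`, or a channel label carried by one of the masks.
#' @inheritParams coloc_percent
#' @return A `coloc_result` (with `label_C` field).
#' @export
coloc_threeway <- function(mask_A, mask_B, mask_C, normalizer = "A",
                           time_min = NA_real_, cell_id = NA_character_) {
  A <- mask_values(mask_A); B <- mask_values(mask_B); C <- mask_values(mask_C)
  check_same_shape(A, B); check_same_shape(A, C)
  labels <- c(A = mask_label(mask_A, "A"), B = mask_label(mask_B, "B"),
              C = mask_label(mask_C, "C"))
  which_mask <- if (normalizer %in% names(labels)) normalizer
                else names(labels)[match(normalizer, labels)]
  if (is.na(which_mask)) {
    vc_parameter_error(sprintf("normalizer '%s' names none of the masks",
                               normalizer))
  }
  den <- sum(switch(which_mask, A = A, B = B, C = C))
  num <- sum(A * B * C)
  new_coloc_result(
    label_A = labels[["A"]], label_B = labels[["B"]], label_C = labels[["C"]],
    direction = sprintf("threeway_norm_%s", which_mask),
    numerator_px = num, denominator_px = den,
    percent = if (den > 0) 100 * num / den else NA_real_, defined = den > 0,
    null_percent = NA_real_, per_slab = NULL,
    time_min = time_min, cell_id = cell_id)
}

#' Rotate a mask or matrix by 180 degrees in-plane
#'
#' Index reversal on both axes; exact for even and odd dimensions.
#'
#' @param m A matrix or [binary_mask()].
#' @return Object of the same type, rotated.
#' @export
rotate180 <- function(m) {
  if (inherits(m, "binary_mask")) {
    m$values <- rotate180(m$values)
    return(m)
  }
  m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
}

#' Rotation null control for co-localization
#'
#' Estimates non-specific (chance) co-localization by rotating one
#' binary channel by 180 degrees and re-evaluating the same overlap
#' equation. The returned result carries the plain percentage in
#' `percent` and the rotation control in `null_percent`.
#'
#' @inheritParams coloc_percent
#' @param rotate Which mask to rotate, `"B"` (default) or `"A"`.
#' @return A `coloc_result` with `null_percent` filled in.
#' @export
rotation_null <- function(mask_A, mask_B,
                          direction = c("B_with_A", "A_with_B"),
                          rotate = c("B", "A"),
                          time_min = NA_real_, cell_id = NA_character_) {
  direction <- match.arg(direction)
  rotate <- match.arg(rotate)
  res <- coloc_percent(mask_A, mask_B, direction, time_min, cell_id)
  rotated <- if (rotate == "B") {
    coloc_percent(mask_A, rotate180(mask_B), direction, time_min, cell_id)
  } else {
    coloc_percent(rotate180(mask_A), mask_B, direction, time_min, cell_id)
  }
  res$null_percent <- rotated$percent
  res$null_numerator_px <- rotated$numerator_px
  res
}

#' Project a z-stack channel into thicker optical slabs
#'
#' Groups consecutive z slices into slabs of nominal thickness
#' `slab_nm` (default 500 nm) and combines each group by maximum
#' intensity projection, which preserves punctate peaks better than a
#' mean for a spot-matched detector. A trailing partial group is kept
#' and flagged.
#'
#' @param stack An [image_stack()] with more than one z slice and a
#'   known `z_spacing_nm`.
#' @param channel Channel label or index.
#' @param slab_nm Slab thickness in nm, at least `z_spacing_nm`.
#' @return List of 2D planes with attributes `partial` (logical per
#'   slab) and `n_slices` (integer per slab).
#' @export
slab_project <- function(stack, channel, slab_nm = 500) {
  nz <- n_slices(stack)
  if (nz == 1L || is.na(stack$z_spacing_nm)) {
    vc_geometry_error(
      "stack is 2D; use the single plane directly instead of slab projection")
  }
  if (slab_nm < stack$z_spacing_nm) {
    vc_parameter_error("slab_nm must be at least z_spacing_nm")
  }
  n_per <- max(1L, as.integer(round(slab_nm / stack$z_spacing_nm)))
  groups <- split(seq_len(nz), ceiling(seq_len(nz) / n_per))
  arr <- get_channel(stack, channel)
  planes <- lapply(groups, function(g) {
    Reduce(pmax, lapply(g, function(z) arr[z, , ]))
  })
  names(planes) <- NULL
  attr(planes, "n_slices") <- unname(lengths(groups))
  attr(planes, "partial") <- unname(lengths(groups) < n_per)
  planes
}

# resolve the threshold for one channel from its filtered values
# (a matrix for slab scope, or all slabs' values pooled for stack scope)
resolve_threshold <- function(filtered, threshold, label) {
  val <- threshold$value
  if (!is.null(val)) {
    if (is.list(val) || !is.null(names(val))) val <- val[[label]]
    if (!is.null(val) && !is.na(val)) return(as.numeric(val))
  }
  method <- threshold$method %||% "otsu-positive"
  if (method == "otsu-positive" && !any(filtered > 0)) {
    return(Inf)  # nothing detectable: empty mask rather than noise speckle
  }
  auto_threshold(filtered, method = method, q = threshold$quantile_q)
}

#' Whole-cell co-localization of two channels
#'
#' Runs the full measurement on one stack: each channel is projected
#' into 500 nm slabs (a 2D stack is treated as a single slab),
#' DOG-filtered, thresholded and binarized per slab; numerator and
#' denominator pixel counts are then pooled over all slabs before the
#' ratio is formed ("integrated for the whole cell"), which weights
#' slabs by signal content and stays well-defined when some slabs are
#' empty. The 180-degree rotation null is pooled the same way.
#'
#' @param stack An [image_stack()] containing both channels.
#' @param label_A,label_B Channel labels (A is the reference; the
#'   default direction reports the fraction of B overlapping A).
#' @param params [dog_params()].
#' @param threshold List with `method` (`"otsu-positive"` or
#'   `"quantile"`), optional fixed `value` (scalar or named per
#'   channel), `quantile_q`, and `scope`: `"stack"` (default) derives
#'   one global threshold per channel from the filtered values of all
#'   slabs pooled, so slabs devoid of signal are not thresholded into
#'   noise speckle; `"slab"` re-derives the threshold per slab.
#' @param slab_nm Slab thickness, nm.
#' @param direction,rotate Passed to the overlap and null computations.
#' @param aggregate `"pooled"` (default; pool pixel counts across
#'   slabs) or `"mean"` (average the per-slab percentages over slabs
#'   with a non-zero denominator; kept for sensitivity analysis).
#' @param filter_per_slice If `TRUE`, DOG-filter each raw z slice and
#'   maximum-project the filtered slices within a slab, instead of the
#'   default project-then-filter.
#' @return A `coloc_result` with per-slab detail in `$per_slab`.
#' @export
cell_coloc <- function(stack, label_A, label_B, params = dog_params(),
                       threshold = list(method = "otsu-positive"),
                       slab_nm = 500,
                       direction = c("B_with_A", "A_with_B"),
                       rotate = c("B", "A"),
                       aggregate = c("pooled", "mean"),
                       filter_per_slice = FALSE) {
  direction <- match.arg(direction)
  rotate <- match.arg(rotate)
  aggregate <- match.arg(aggregate)
  label_A <- stack$channel_labels[channel_index(stack, label_A)]
  label_B <- stack$channel_labels[channel_index(stack, label_B)]
  px <- stack$pixel_size_nm

  slab_planes <- function(lab) {
    if (n_slices(stack) == 1L) {
      p <- list(channel_plane(stack, lab, 1L))
      attr(p, "n_slices") <- 1L
      attr(p, "partial") <- FALSE
      return(p)
    }
    if (!filter_per_slice) return(slab_project(stack, lab, slab_nm))
    # filter every z slice first, then max-project the filtered slices
    raw <- slab_project(stack, lab, slab_nm)  # grouping geometry only
    nz <- n_slices(stack)
    n_per <- max(1L, as.integer(round(slab_nm / stack$z_spacing_nm)))
    groups <- split(seq_len(nz), ceiling(seq_len(nz) / n_per))
    planes <- lapply(groups, function(g) {
      Reduce(pmax, lapply(g, function(z) {
        dog_filter(channel_plane(stack, lab, z), params, px)
      }))
    })
    names(planes) <- NULL
    attr(planes, "n_slices") <- attr(raw, "n_slices")
    attr(planes, "partial") <- attr(raw, "partial")
    attr(planes, "prefiltered") <- TRUE
    planes
  }

  planes_A <- slab_planes(label_A)
  planes_B <- slab_planes(label_B)
  prefiltered <- isTRUE(attr(planes_A, "prefiltered"))
  n_slab <- length(planes_A)

  per_slab <- data.frame(
    slab = seq_len(n_slab),
    n_slices = as.integer(attr(planes_A, "n_slices")),
    partial = as.logical(attr(planes_A, "partial")),
    numerator_px = 0L, den_A_px = 0L, den_B_px = 0L,
    null_numerator_px = 0L,
    threshold_A = NA_real_, threshold_B = NA_real_)

  filt_A <- lapply(planes_A, function(p) {
    if (prefiltered) p else dog_filter(p, params, px)
  })
  filt_B <- lapply(planes_B, function(p) {
    if (prefiltered) p else dog_filter(p, params, px)
  })

  scope <- threshold$scope %||% "stack"
  if (identical(scope, "stack")) {
    stack_tA <- resolve_threshold(unlist(filt_A), threshold, label_A)
    stack_tB <- resolve_threshold(unlist(filt_B), threshold, label_B)
  }

  for (s in seq_len(n_slab)) {
    fA <- filt_A[[s]]
    fB <- filt_B[[s]]
    if (identical(scope, "stack")) {
      tA <- stack_tA; tB <- stack_tB
    } else {
      tA <- resolve_threshold(fA, threshold, label_A)
      tB <- resolve_threshold(fB, threshold, label_B)
    }
    mA <- (fA > tA) * 1L
    mB <- (fB > tB) * 1L
    mRot <- if (rotate == "B") rotate180(mB) else mB
    mARot <- if (rotate == "A") rotate180(mA) else mA
    per_slab$numerator_px[s] <- sum(mA * mB)
    per_slab$den_A_px[s] <- sum(mA)
    per_slab$den_B_px[s] <- sum(mB)
    per_slab$null_numerator_px[s] <- sum(mARot * mRot)
    per_slab$threshold_A[s] <- tA
    per_slab$threshold_B[s] <- tB
  }

  num <- sum(per_slab$numerator_px)
  null_num <- sum(per_slab$null_numerator_px)
  den_A <- sum(per_slab$den_A_px)
  den_B <- sum(per_slab$den_B_px)
  den <- if (direction == "B_with_A") den_B else den_A
  den_slab <- if (direction == "B_with_A") per_slab$den_B_px else per_slab$den_A_px

  if (aggregate == "pooled") {
    percent <- if (den > 0) 100 * num / den else NA_real_
    null_percent <- if (den > 0) 100 * null_num / den else NA_real_
  } else {
    ok <- den_slab > 0
    percent <- if (any(ok)) mean(100 * per_slab$numerator_px[ok] / den_slab[ok]) else NA_real_
    null_percent <- if (any(ok)) mean(100 * per_slab$null_numerator_px[ok] / den_slab[ok]) else NA_real_
  }

  new_coloc_result(
    label_A = label_A, label_B = label_B, direction = direction,
    numerator_px = num, denominator_px = den,
    percent = percent, defined = den > 0,
    percent_B_with_A = if (den_B > 0) 100 * num / den_B else NA_real_,
    percent_A_with_B = if (den_A > 0) 100 * num / den_A else NA_real_,
    null_percent = null_percent, null_numerator_px = null_num,
    per_slab = per_slab, aggregate = aggregate,
    threshold_A = per_slab$threshold_A, threshold_B = per_slab$threshold_B,
    time_min = stack$time_min, condition = stack$condition,
    cell_id = stack$cell_id)
}

#' Flatten co-localization results into a tidy table
#'
#' One row per result, suitable for CSV output and for
#' [summarize_timecourse()]. Per-slab thresholds are ";"-joined for
#' provenance.
#'
#' @param results A `coloc_result` or a list of them.
#' @return A data.frame.
#' @export
coloc_results_df <- function(results) {
  if (inherits(results, "coloc_result")) results <- list(results)
  if (!length(results)) {
    vc_degenerate_error("no co-localization results supplied")
  }
  fmt_thr <- function(x) paste(formatC(x, format = "g", digits = 6),
                               collapse = ";")
  rows <- lapply(results, function(r) {
    data.frame(
      cell_id = r$cell_id %||% NA_character_,
      condition = r$condition %||% NA_character_,
      time_min = r$time_min %||% NA_real_,
      label_A = r$label_A, label_B = r$label_B,
      direction = r$direction,
      numerator_px = r$numerator_px, denominator_px = r$denominator_px,
      percent = r$percent, null_percent = r$null_percent,
      defined = isTRUE(r$defined),
      threshold_A = fmt_thr(r$threshold_A %||% NA_real_),
      threshold_B = fmt_thr(r$threshold_B %||% NA_real_),
      n_slabs = if (is.null(r$per_slab)) 1L else nrow(r$per_slab),
      partial_slab = if (is.null(r$per_slab)) FALSE else any(r$per_slab$partial),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
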