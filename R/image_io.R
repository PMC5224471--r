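#' Write a calibrated stack to TIFF
#'
#' Pages are written channel-major (all z of channel 1, then channel 2,
#' ...) with lossless deflate compression. Because baseline TIFF has no
#' slot for physical calibration or acquisition annotations, these are
#' stored in a JSON metadata sidecar (`<path>.json`) written next to the
#' image; [load_stack()] reads it back transparently. Integer-valued
#' data up to 16 bits round-trips bit-exactly; other data is stored as
#' 32-bit float scaled by a power of two (exact for integers below
#' 2^24, within float precision otherwise).
#'
#' @param stack An [image_stack()].
#' @param path Destination file path (`.tif`).
#' @return The path, invisibly.
#' @export
save_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) {
    vc_validation_error("save_stack expects an image_stack")
  }
  # re-validate: objects can be edited after construction
  if (!all(is.finite(stack$intensities)) || any(stack$intensities < 0)) {
    vc_validation_error("stack intensities must be finite and non-negative")
  }
  d <- dim(stack$intensities)
  vmax <- max(stack$intensities, 0)
  int_like <- all(stack$intensities == round(stack$intensities))
  if (int_like && vmax <= 65535) {
    mode <- "uint16"; scale <- 65535; bits <- 16L
  } else {
    mode <- "float32"
    scale <- 2^max(0, ceiling(log2(max(vmax, 1))))
    bits <- 32L
  }
  pages <- vector("list", d[1L] * d[2L])
  k <- 1L
  for (ch in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      pages[[k]] <- matrix(stack$intensities[ch, z, , ] / scale,
                           nrow = d[3L], ncol = d[4L])
      k <- k + 1L
    }
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "deflate"),
    error = function(e) vc_io_error(sprintf("cannot write '%s': %s", path,
                                            conditionMessage(e))))
  meta <- list(
    format = "vesicoloc-stack", format_version = 1L,
    n_channels = d[1L], n_z = d[2L], n_y = d[3L], n_x = d[4L],
    pixel_size_nm = stack$pixel_size_nm,
    z_spacing_nm = stack$z_spacing_nm,
    channel_labels = as.list(stack$channel_labels),
    time_min = stack$time_min,
    condition = stack$condition,
    cell_id = stack$cell_id,
    encoding = list(mode = mode, scale = scale)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Load a calibrated stack from TIFF / OME-TIFF
#'
#' Calibration and annotations are resolved per field, in priority
#' order: explicit `overrides`, the JSON sidecar written by
#' [save_stack()], OME-XML in the TIFF ImageDescription tag, and
#' finally classic TIFF resolution tags (lateral pixel size only). A
#' disagreement between OME-XML and resolution tags is reported with a
#' message and OME-XML wins. Pixel size is never defaulted: if no
#' source provides it, loading fails with a calibration error.
#'
#' @param path TIFF file to read.
#' @param overrides Named list of fields to force, any of
#'   `pixel_size_nm`, `z_spacing_nm`, `channel_labels`, `n_channels`,
#'   `time_min`, `condition`, `cell_id`.
#' @param annotations Optional annotation table (see
#'   [read_annotation_table()]); the row whose `file` matches
#'   `basename(path)` supplies overrides (explicit `overrides` still
#'   win).
#' @return An [image_stack()].
#' @export
load_stack <- function(path, overrides = list(), annotations = NULL) {
  if (!file.exists(path)) vc_io_error(sprintf("file not found: %s", path))
  if (!is.null(annotations)) {
    ann <- annotation_overrides(annotations, path)
    for (nm in names(ann)) {
      if (is.null(overrides[[nm]])) overrides[[nm]] <- ann[[nm]]
    }
  }
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  }
  # float pages must not be reinterpreted as raw integers; integer pages
  # are kept as stored so 16-bit data round-trips bit-exactly
  hdr <- tiff::readTIFF(path, info = TRUE, payload = FALSE)
  bits <- if (is.data.frame(hdr) && "bits.per.sample" %in% names(hdr)) {
    hdr$bits.per.sample[1L]
  } else NA_integer_
  is_float <- identical(meta$encoding$mode, "float32") ||
    (is.null(meta$encoding$mode) && identical(as.integer(bits), 32L))
  pages <- suppressWarnings(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = !is_float))
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1)))) {
    vc_validation_error("only single-sample (grayscale) TIFF pages are supported")
  }
  desc <- attr(pages[[1L]], "description")
  ome <- if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE)) {
    parse_ome_description(desc)
  } else NULL
  res_px <- pixel_size_from_resolution(attributes(pages[[1L]]))
  if (!is.null(ome$pixel_size_nm) && !is.null(res_px) &&
      abs(ome$pixel_size_nm - res_px) > 1e-6 * ome$pixel_size_nm) {
    message(sprintf(
      "pixel size conflict in %s: OME-XML %g nm vs resolution tag %g nm; using OME-XML",
      basename(path), ome$pixel_size_nm, res_px))
  }

  pick <- function(field, ...) {
    for (v in list(overrides[[field]], meta[[field]], ome[[field]], ...)) {
      if (!is.null(v) && !all(is.na(v))) return(v)
    }
    NULL
  }

  pixel_size_nm <- pick("pixel_size_nm", res_px)
  if (is.null(pixel_size_nm)) {
    vc_calibration_error(sprintf(
      "no pixel size for '%s': supply overrides$pixel_size_nm (metadata absent)",
      basename(path)))
  }
  z_spacing_nm <- pick("z_spacing_nm")
  channel_labels <- pick("channel_labels")
  if (!is.null(channel_labels)) channel_labels <- unlist(channel_labels)

  n_pages <- length(pages)
  n_ch <- overrides$n_channels %||% meta$n_channels %||%
    (if (!is.null(channel_labels)) length(channel_labels) else 1L)
  n_ch <- as.integer(n_ch)
  if (n_pages %% n_ch != 0L) {
    vc_annotation_error(sprintf(
      "%d TIFF pages cannot be split into %d channels", n_pages, n_ch))
  }
  n_z <- n_pages %/% n_ch

  # undo the on-disk scaling recorded by save_stack
  decode <- function(m) m
  if (!is.null(meta$encoding)) {
    sc_fac <- meta$encoding$scale
    if (identical(meta$encoding$mode, "uint16")) {
      decode <- function(m) m  # as.is = TRUE yields the stored integers
    } else {
      decode <- function(m) m * sc_fac
    }
  }
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  arr <- array(0, dim = c(n_ch, n_z, ny, nx))
  k <- 1L
  for (ch in seq_len(n_ch)) {
    for (z in seq_len(n_z)) {
      arr[ch, z, , ] <- decode(pages[[k]])
      k <- k + 1L
    }
  }

  image_stack(arr,
              pixel_size_nm = pixel_size_nm,
              channel_labels = channel_labels,
              z_spacing_nm = z_spacing_nm %||% NA_real_,
              time_min = pick("time_min") %||% NA_real_,
              condition = pick("condition") %||% NA_character_,
              cell_id = pick("cell_id") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# OME length units to nm
ome_unit_nm <- c("nm" = 1, "um" = 1000, "µm" = 1000, "μm" = 1000,
                 "mm" = 1e6)

#' Parse pixel geometry from an OME-XML ImageDescription
#'
#' Extracts `PhysicalSizeX` / `PhysicalSizeZ` (converted to nm; the OME
#' default unit is micrometres) and channel names from an OME-XML
#' string, tolerating namespace prefixes.
#'
#' @param xml OME-XML string.
#' @return List with any of `pixel_size_nm`, `z_spacing_nm`,
#'   `channel_labels` that were present.
#' @export
parse_ome_description <- function(xml) {
  doc <- tryCatch(xml2::read_xml(xml), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  out <- list()
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (!inherits(px, "xml_missing")) {
    to_nm <- function(value_attr, unit_attr) {
      v <- xml2::xml_attr(px, value_attr)
      if (is.na(v)) return(NULL)
      u <- xml2::xml_attr(px, unit_attr)
      f <- if (is.na(u)) 1000 else ome_unit_nm[u]
      if (is.na(f)) return(NULL)
      as.numeric(v) * unname(f)
    }
    out$pixel_size_nm <- to_nm("PhysicalSizeX", "PhysicalSizeXUnit")
    out$z_spacing_nm <- to_nm("PhysicalSizeZ", "PhysicalSizeZUnit")
  }
  chn <- xml2::xml_find_all(doc, ".//*[local-name()='Channel']")
  if (length(chn)) {
    nms <- xml2::xml_attr(chn, "Name")
    if (!anyNA(nms)) out$channel_labels <- nms
  }
  out
}

# lateral pixel size (nm) from classic TIFF resolution tags, if usable
pixel_size_from_resolution <- function(at) {
  xres <- at[["x.resolution"]]
  unit <- at[["resolution.unit"]]
  if (is.null(xres) || is.null(unit) || !is.numeric(xres) || xres <= 0) {
    return(NULL)
  }
  per_nm <- switch(unit, inch = 2.54e7, cm = 1e7, NULL)
  if (is.null(per_nm)) return(NULL)
  per_nm / xres
}

#' Read a sidecar annotation table
#'
#' Plain TIFF has no standard slot for time point, condition or cell
#' identity, so these may be supplied as a CSV keyed by file name with
#' columns `file` (required) and any of `channel_labels`
#' (";"-separated), `time_min`, `condition`, `cell_id`,
#' `pixel_size_nm`, `z_spacing_nm`.
#'
#' @param path CSV file.
#' @return A data.frame.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"file" %in% names(df)) {
    vc_annotation_error("annotation table must have a 'file' column")
  }
  df
}

annotation_overrides <- function(ann, path) {
  i <- match(basename(path), basename(as.character(ann$file)))
  if (is.na(i)) return(list())
  out <- list()
  for (nm in c("time_min", "condition", "cell_id", "pixel_size_nm",
               "z_spacing_nm")) {
    if (nm %in% names(ann) && !is.na(ann[[nm]][i])) out[[nm]] <- ann[[nm]][i]
  }
  if ("channel_labels" %in% names(ann) && !is.na(ann$channel_labels[i])) {
    out$channel_labels <- strsplit(ann$channel_labels[i], ";", fixed = TRUE)[[1L]]
  }
  out
}
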