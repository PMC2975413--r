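# image and report I/O; no science here

#' Read a grayscale microscopy image
#'
#' Loads an 8- or 16-bit PNG or TIFF, converting RGB to luminance
#' (ITU-R 601 weights 0.299/0.587/0.114) and rescaling the full bit depth to
#' the `[0, 255]` intensity scale used throughout the package.
#'
#' @param path path to a PNG or TIFF file.
#' @return numeric matrix (rows x cols) of intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  )
  img <- if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]  # gray + alpha
    }
  } else {
    arr
  }
  img <- img * 255
  assert_gray_image(img)
}

#' Write a grayscale image as 8-bit PNG
#'
#' Intensities are rounded to integers; integer-valued images round-trip
#' exactly through [read_image()].
#'
#' @param image numeric matrix with values in `[0, 255]`.
#' @param path output path (`.png`).
#' @export
write_image <- function(image, path) {
  assert_gray_image(image)
  png::writePNG(round(image) / 255, path)
  invisible(path)
}

#' Write a label map as 16-bit TIFF
#'
#' @param labels integer matrix of non-negative labels (max 65535).
#' @param path output path (`.tif`/`.tiff`).
#' @export
write_label_map <- function(labels, path) {
  if (any(labels < 0) || max(labels) > 65535)
    stop("labels must be in [0, 65535]", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path path to a 16-bit grayscale TIFF.
#' @return integer matrix of labels.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path))
    stop("cannot read label map: no such file: ", path, call. = FALSE)
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  matrix(as.integer(round(arr * 65535)), nrow(arr), ncol(arr))
}

#' Write the per-granule measurement report
#'
#' Writes one CSV row per segment with the columns `label`, `area_px`,
#' `perimeter_px`, `roundness`, `centroid_row`, `centroid_col`,
#' `equivalent_diameter_px`, `mean_intensity`, `intensity_variance`,
#' `classification`. An empty record table yields a header-only file.
#'
#' @param records segment record data frame from [measure_regions()].
#' @param path output CSV path.
#' @param renumber_from_one if `TRUE`, report labels starting at 1 with the
#'   background counted as segment 1 (some published figures use that
#'   convention); default keeps the internal labels.
#' @export
write_report <- function(records, path, renumber_from_one = FALSE) {
  cols <- c(label = "label", area_px = "area", perimeter_px = "perimeter",
            roundness = "roundness", centroid_row = "centroid_row",
            centroid_col = "centroid_col",
            equivalent_diameter_px = "equivalent_diameter",
            mean_intensity = "mean_intensity",
            intensity_variance = "intensity_variance",
            classification = "classification")
  out <- as.data.frame(lapply(cols, function(nm) {
    if (nm %in% names(records)) records[[nm]]
    else rep(NA, nrow(records))
  }))
  names(out) <- names(cols)
  if (renumber_from_one && nrow(out)) out$label <- out$label + 1L
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an RGB overlay of a label map on the source image
#'
#' Foreground segments are tinted with distinct hues over the grayscale
#' image; background keeps the original intensity.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param labels integer label matrix of the same shape.
#' @param path output PNG path.
#' @param alpha tint strength in `[0, 1]`.
#' @export
write_overlay <- function(image, labels, path, alpha = 0.5) {
  assert_gray_image(image)
  assert_same_shape(image, labels, "image and labels")
  g <- image / 255
  k <- max(labels)
  rgb <- array(rep(g, 3L), c(nrow(g), ncol(g), 3L))
  if (k > 0) {
    cols <- grDevices::col2rgb(grDevices::hcl.colors(max(k, 3L), "Dark 3")) / 255
    for (l in seq_len(k)) {
      sel <- labels == l
      if (!any(sel)) next
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[sel] <- (1 - alpha) * plane[sel] + alpha * cols[ch, l]
        rgb[, , ch] <- plane
      }
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
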