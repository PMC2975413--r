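# chamfer distance transform and Meyer watershed segmentation

#' Chamfer distance transform
#'
#' Two-pass (forward/backward raster) chamfer distance from each foreground
#' pixel to the nearest background pixel, with integer step weights
#' (default 3 orthogonal / 4 diagonal) divided by the orthogonal weight so
#' values approximate Euclidean pixel units. Pixels outside the image border
#' count as background, so granules touching the border stay bounded.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param weights integer pair `(orthogonal, diagonal)`.
#' @return numeric matrix of distances; exactly 0 on background.
#' @export
chamfer_distance <- function(mask, weights = c(3L, 4L)) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (length(weights) != 2L || any(weights <= 0))
    stop("weights must be two positive integers", call. = FALSE)
  d <- chamfer_dt_cpp(mask, as.integer(weights[1]), as.integer(weights[2]))
  d / weights[1]
}

#' Watershed segmentation of a distance map
#'
#' Partitions the foreground into segments by Meyer priority-queue flooding
#' of the negated distance map: each regional-maximum plateau of the distance
#' map (granule centres) seeds one catchment basin, and basins grow outward
#' from high to low distance, restricted to the foreground. No maxima
#' suppression is applied — spurious maxima become oversegments and are dealt
#' with downstream. Flooding ties are first-come in deterministic raster
#' order, so results are reproducible.
#'
#' @param dmap distance map from [chamfer_distance()].
#' @param mask the foreground mask the map was computed from.
#' @return an object of class `watershed_result`: list with `labels`
#'   (integer matrix, 0 = background), `n_segments`, and `seeds` (data frame
#'   of one representative pixel per seed plateau).
#' @export
watershed_segment <- function(dmap, mask) {
  assert_same_shape(dmap, mask, "distance map and mask")
  if (!any(mask)) {
    return(structure(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                          n_segments = 0L,
                          seeds = data.frame(label = integer(), row = integer(),
                                             col = integer())),
                     class = "watershed_result"))
  }
  seeds <- regional_max_seeds_cpp(dmap, mask)
  labels <- meyer_flood_cpp(dmap, mask, seeds)
  k <- max(seeds)
  idx <- which(seeds > 0, arr.ind = TRUE)
  lab <- seeds[seeds > 0]
  first <- !duplicated(lab)
  seed_df <- data.frame(label = lab[first], row = idx[first, 1],
                        col = idx[first, 2])
  seed_df <- seed_df[order(seed_df$label), , drop = FALSE]
  rownames(seed_df) <- NULL
  structure(list(labels = labels, n_segments = k, seeds = seed_df),
            class = "watershed_result")
}

#' @export
print.watershed_result <- function(x, ...) {
  cat(sprintf("watershed: %d segments over %d foreground pixels\n",
              x$n_segments, sum(x$labels > 0)))
  invisible(x)
}
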