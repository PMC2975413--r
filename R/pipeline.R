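# end-to-end orchestration

#' Run the full granule segmentation pipeline
#'
#' Executes, in order: iterative thresholding, binarization, chamfer distance
#' transform, Meyer watershed, per-segment morphometry, the roundness screen,
#' GVF critical-point detection for the segments the screen left pending,
#' final core/oversegment classification, grouping by foreground blob, and
#' fuzzy c-means merging of oversegments into cores. Every intermediate is
#' retained in the result. The pipeline is fully deterministic given the
#' image and the configuration.
#'
#' @param image intensity matrix in `[0, 255]` (see [read_image()]).
#' @param config a [seg_config()].
#' @param verbose emit progress messages.
#' @return object of class `pipeline_result` with elements
#'   `threshold_state`, `mask`, `distance`, `watershed`, `records`
#'   (classified segment records), `critical_points`, `groups`, `merge`,
#'   `merged_labels`, `report` (per-granule measurements on the merged
#'   map), `n_granules`, `config`.
#' @export
run_pipeline <- function(image, config = seg_config(), verbose = FALSE) {
  assert_gray_image(image)
  stopifnot(inherits(config, "seg_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  ts <- iterative_threshold(image, t0 = config$threshold$t0,
                            eps = config$threshold$eps)
  mask <- if (ts$degenerate) {
    warning("blank image: no foreground found")
    matrix(FALSE, nrow(image), ncol(image))
  } else {
    binarize(image, ts, config$threshold$polarity)
  }
  say("threshold converged: T0 = %.1f -> T = %.2f (%d iterations)",
      ts$t0, ts$t, ts$n_iter)

  if (!any(mask)) {
    if (!ts$degenerate) warning("empty foreground after thresholding")
    empty <- matrix(0L, nrow(image), ncol(image))
    recs <- measure_regions(empty, image)
    return(structure(list(threshold_state = ts, mask = mask,
                          distance = matrix(0, nrow(image), ncol(image)),
                          watershed = watershed_segment(
                            matrix(0, nrow(image), ncol(image)), mask),
                          records = recs,
                          critical_points = NULL,
                          groups = list(),
                          merge = NULL,
                          merged_labels = empty, report = recs,
                          n_granules = 0L, config = config),
                     class = "pipeline_result"))
  }

  dmap <- chamfer_distance(mask, config$chamfer$weights)
  ws <- watershed_segment(dmap, mask)
  say("watershed: %d segments", ws$n_segments)

  stage <- run_merge_stage(image, ws$labels, config, verbose = verbose)

  structure(c(list(threshold_state = ts, mask = mask, distance = dmap,
                   watershed = ws), stage, list(config = config)),
            class = "pipeline_result")
}

#' Run the classification and merge stages on an existing label map
#'
#' The tail of [run_pipeline()]: morphometry, roundness screen, GVF
#' critical points, classification, grouping, and fuzzy c-means merging.
#' Useful for merge-only processing of a precomputed watershed label map;
#' by construction a full pipeline run equals this function applied to its
#' own watershed output.
#'
#' @param image intensity matrix the labels were computed from.
#' @param labels watershed label matrix (0 = background).
#' @param config a [seg_config()].
#' @param verbose emit progress messages.
#' @return list with `records`, `critical_points`, `groups`, `merge`,
#'   `merged_labels`, `report`, `n_granules`.
#' @export
run_merge_stage <- function(image, labels, config = seg_config(),
                            verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  labels <- compact_labels(labels)
  recs <- measure_regions(labels, image)
  recs <- flag_by_roundness(recs, config$roundness$threshold,
                            config$roundness$min_area)

  cps <- NULL
  if (any(recs$classification == "pending")) {
    f <- edge_map(image, config$gvf$sigma)
    field <- compute_gvf(f, mu = config$gvf$mu,
                         max_iter = config$gvf$max_iter, tol = config$gvf$tol)
    cps <- detect_critical_points(
      field, recs, labels,
      sim_threshold = config$critical$sim_threshold,
      min_directions = config$critical$min_directions,
      radius_factor = config$critical$search_radius_factor,
      probe_radius = config$critical$probe_radius)
  }
  recs <- classify_segments(recs, if (is.null(cps))
    data.frame(label = integer(), found = logical()) else cps)
  say("classification: %d core, %d oversegment",
      sum(recs$classification == "core"),
      sum(recs$classification == "oversegment"))

  groups <- build_merge_groups(labels, labels > 0, recs)
  mg <- merge_oversegments(labels, groups, recs,
                           weights = config$fcm$weights, m = config$fcm$m,
                           tol = config$fcm$tol,
                           max_iter = config$fcm$max_iter)
  say("merge: %d oversegments merged, %d granules",
      nrow(mg$assignments), mg$n_granules)

  report <- measure_regions(mg$labels, image)
  if (nrow(report)) {
    origin <- mg$label_origin$origin[match(report$label, mg$label_origin$label)]
    is_core <- origin %in% recs$label[recs$classification == "core"]
    report$classification <- ifelse(is_core, "core", "oversegment")
    report$has_critical_point <-
      recs$has_critical_point[match(origin, recs$label)]
  }

  list(records = recs, critical_points = cps, groups = groups, merge = mg,
       merged_labels = mg$labels, report = report,
       n_granules = mg$n_granules)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("granule segmentation pipeline\n")
  cat(sprintf("  threshold: T0 = %.1f -> T = %.2f\n",
              x$threshold_state$t0, x$threshold_state$t))
  cat(sprintf("  watershed segments: %d\n", x$watershed$n_segments))
  cat(sprintf("  core segments (granules): %d\n", x$n_granules))
  if (!is.null(x$merge))
    cat(sprintf("  oversegments merged: %d\n", nrow(x$merge$assignments)))
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Writes the merged label map (16-bit TIFF), an RGB overlay PNG, the
#' per-granule CSV report, and a JSON sidecar recording the converged
#' threshold, the segment table, and the merge decisions. With
#' `save_intermediates`, also writes the binary mask, distance map and raw
#' watershed labels.
#'
#' @param result a `pipeline_result`.
#' @param image the input image (for the overlay).
#' @param outdir output directory (created if missing).
#' @param stem file-name stem.
#' @param save_intermediates also write stage artifacts.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, image, outdir, stem = "granules",
                                   save_intermediates = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(suffix) file.path(outdir, paste0(stem, suffix))
  write_label_map(result$merged_labels, p("_labels.tif"))
  write_overlay(image, result$merged_labels, p("_overlay.png"))
  write_report(result$report, p("_report.csv"))
  sidecar <- list(
    threshold = list(t0 = result$threshold_state$t0,
                     t = result$threshold_state$t,
                     n_iter = result$threshold_state$n_iter),
    n_segments = result$watershed$n_segments,
    n_granules = result$n_granules,
    segments = result$records,
    merges = if (!is.null(result$merge)) result$merge$assignments else NULL)
  jsonlite::write_json(sidecar, p("_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (save_intermediates) {
    write_image(255 * result$mask, p("_mask.png"))
    dmax <- max(result$distance)
    write_image(if (dmax > 0) 255 * result$distance / dmax
                else result$distance, p("_distance.png"))
    write_label_map(result$watershed$labels, p("_watershed.tif"))
  }
  invisible(outdir)
}
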