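# seeded synthetic granule scenes with ground truth

#' Specify a synthetic granule scene
#'
#' Describes a bright-field-like scene: dark, round (optionally mildly
#' elliptical) granules on a light background, smoothed edges, additive
#' Gaussian noise, and a known ground-truth label per granule. The defaults
#' mimic stained starch micrographs: foreground/background 60/180 gives the
#' bimodal histogram such images show, noise_sigma 5 is small against that
#' 120-unit contrast, and radii of 15–30 px correspond to granules tens of
#' pixels across.
#'
#' @param n_granules number of granules to place.
#' @param radius_range `(min, max)` nominal radius in pixels.
#' @param overlap_fraction maximum allowed deficit of the centre distance
#'   relative to the radius sum, in `[0, 1)`: 0 forbids contact, 0.3 allows
#'   centres as close as 70% of the radius sum.
#' @param fg_intensity,bg_intensity granule and background gray levels
#'   (foreground must be darker).
#' @param noise_sigma additive Gaussian noise s.d. (intensity units).
#' @param blur_sigma Gaussian edge smoothing in pixels.
#' @param image_size `(height, width)` in pixels.
#' @param ellipse_ratio maximum major/minor axis ratio (1 = circles).
#' @param seed RNG seed; the same spec regenerates the scene bit-for-bit.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(n_granules = 6L, radius_range = c(15, 30),
                       overlap_fraction = 0.3, fg_intensity = 60,
                       bg_intensity = 180, noise_sigma = 5, blur_sigma = 1,
                       image_size = c(320L, 320L), ellipse_ratio = 1.0,
                       seed = 1L) {
  if (fg_intensity >= bg_intensity)
    stop("granules must be darker than the background", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  if (length(radius_range) != 2L || radius_range[1] > radius_range[2] ||
      radius_range[1] <= 0)
    stop("radius_range must be a valid (min, max) pair", call. = FALSE)
  if (ellipse_ratio < 1)
    stop("ellipse_ratio must be >= 1", call. = FALSE)
  structure(list(n_granules = as.integer(n_granules),
                 radius_range = radius_range,
                 overlap_fraction = overlap_fraction,
                 fg_intensity = fg_intensity, bg_intensity = bg_intensity,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 image_size = as.integer(image_size),
                 ellipse_ratio = ellipse_ratio,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a synthetic granule scene
#'
#' Places granules by rejection sampling honouring the spec's overlap limit,
#' rasterizes dark granules on the light background, applies Gaussian blur
#' then additive Gaussian noise clipped to `[0, 255]`. Ground-truth labels
#' assign each overlap pixel to the nearer granule centre, mirroring the
#' distance-based cut a watershed would make.
#'
#' Granules are rendered as absorbers under transmitted light: each granule
#' covering a pixel multiplies the transmitted intensity by
#' `fg_intensity / bg_intensity`, so a pixel under one granule has intensity
#' `fg_intensity` and a pixel where two granules overlap is darker
#' (Beer-Lambert stacking). Stained granules under bright-field
#' illumination behave this way, and the darker lens at an overlap is what
#' gives each granule of a touching pair its own intensity boundary.
#'
#' @param spec a `scene_spec`.
#' @return object of class `synthetic_scene`: `image`, `truth_labels`,
#'   `centers` (data frame), `radii`, `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  with_seed(spec$seed, {
    placed <- NULL
    for (restart in 1:20) {
      placed <- place_granules(spec, h, w)
      if (!is.null(placed)) break
    }
    if (is.null(placed))
      stop("could not place ", spec$n_granules, " granules; use a larger ",
           "image or fewer/smaller granules", call. = FALSE)

    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    n_cover <- matrix(0L, h, w)
    truth <- matrix(0L, h, w)
    bestd2 <- matrix(Inf, h, w)
    for (i in seq_len(spec$n_granules)) {
      p <- placed[i, ]
      dr <- rr - p["row"]
      dc <- cc - p["col"]
      ca <- cos(p["angle"])
      sa <- sin(p["angle"])
      xa <- dc * ca + dr * sa
      xb <- -dc * sa + dr * ca
      inside <- (xa / p["a"])^2 + (xb / p["b"])^2 <= 1
      d2 <- dr^2 + dc^2
      take <- inside & d2 < bestd2
      truth[take] <- i
      bestd2[take] <- d2[take]
      n_cover <- n_cover + inside
    }

    # transmitted light: each covering granule attenuates by fg/bg
    img <- spec$bg_intensity * (spec$fg_intensity / spec$bg_intensity)^n_cover
    img <- gaussian_blur(img, spec$blur_sigma)
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(h * w, sd = spec$noise_sigma), h, w)
    img <- clamp(img, 0, 255)

    structure(list(image = img, truth_labels = truth,
                   centers = data.frame(label = seq_len(spec$n_granules),
                                        row = placed[, "row"],
                                        col = placed[, "col"]),
                   radii = placed[, "r"], spec = spec),
              class = "synthetic_scene")
  })
}

# rejection-sample granule centres/radii; NULL on failure
place_granules <- function(spec, h, w) {
  n <- spec$n_granules
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("row", "col", "r", "a", "b", "angle")))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:2000) {
      r <- runif(1, spec$radius_range[1], spec$radius_range[2])
      ratio <- runif(1, 1, spec$ellipse_ratio)
      a <- r * sqrt(ratio)           # keep the area near pi * r^2
      margin <- a + 3 * spec$blur_sigma + 2
      if (2 * margin >= min(h, w)) next
      cr <- runif(1, margin, h - margin)
      cl <- runif(1, margin, w - margin)
      if (i > 1) {
        d <- sqrt((out[seq_len(i - 1), "row"] - cr)^2 +
                  (out[seq_len(i - 1), "col"] - cl)^2)
        lim <- (1 - spec$overlap_fraction) * (out[seq_len(i - 1), "r"] + r)
        if (any(d < lim)) next
      }
      out[i, ] <- c(cr, cl, r, a, r / sqrt(ratio), runif(1, 0, pi))
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  out
}

#' Score a predicted label map against ground truth
#'
#' Greedy best-IoU matching between predicted and true granules, reporting
#' the granule count error, per-match IoU, the number of granules resolved
#' at IoU >= 0.5, and split/merge counts (a predicted label that is the best
#' overlap of two true granules counts one merge; two predicted labels whose
#' best overlap is the same true granule count one split).
#'
#' @param pred predicted label matrix.
#' @param truth ground-truth label matrix of the same shape.
#' @return list with `n_pred`, `n_truth`, `count_error`, `matches` (data
#'   frame `pred`, `truth`, `iou`), `n_resolved`, `n_splits`, `n_merges`.
#' @export
score_against_truth <- function(pred, truth) {
  assert_same_shape(pred, truth, "prediction and truth")
  pl <- sort(unique(pred[pred > 0]))
  tl <- sort(unique(truth[truth > 0]))
  sel <- pred > 0 | truth > 0
  tab <- table(factor(pred[sel], levels = pl), factor(truth[sel], levels = tl))
  pa <- tabulate(match(pred[pred > 0], pl), length(pl))
  ta <- tabulate(match(truth[truth > 0], tl), length(tl))

  pairs <- which(tab > 0, arr.ind = TRUE)
  iou <- if (nrow(pairs)) {
    inter <- tab[pairs]
    inter / (pa[pairs[, 1]] + ta[pairs[, 2]] - inter)
  } else numeric(0)
  ord <- order(-iou)
  used_p <- used_t <- logical(0)
  matches <- data.frame(pred = integer(), truth = integer(), iou = numeric())
  taken_p <- rep(FALSE, length(pl))
  taken_t <- rep(FALSE, length(tl))
  for (o in ord) {
    i <- pairs[o, 1]
    j <- pairs[o, 2]
    if (taken_p[i] || taken_t[j]) next
    taken_p[i] <- taken_t[j] <- TRUE
    matches <- rbind(matches, data.frame(pred = pl[i], truth = tl[j],
                                         iou = iou[o]))
  }

  best_p_for_t <- if (length(tl))
    apply(tab, 2, function(col) if (max(col) > 0) which.max(col) else NA)
  else integer(0)
  best_t_for_p <- if (length(pl))
    apply(tab, 1, function(rw) if (max(rw) > 0) which.max(rw) else NA)
  else integer(0)
  n_merges <- sum(pmax(0, table(best_p_for_t[!is.na(best_p_for_t)]) - 1))
  n_splits <- sum(pmax(0, table(best_t_for_p[!is.na(best_t_for_p)]) - 1))

  list(n_pred = length(pl), n_truth = length(tl),
       count_error = length(pl) - length(tl),
       matches = matches,
       n_resolved = sum(matches$iou >= 0.5),
       n_splits = as.integer(n_splits), n_merges = as.integer(n_merges))
}
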