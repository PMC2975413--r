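# shared internal helpers

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop("image has zero size", call. = FALSE)
  if (anyNA(image) || any(!is.finite(image)))
    stop("image contains non-finite values", call. = FALSE)
  if (min(image) < 0 || max(image) > 255)
    stop("image intensities must lie in [0, 255]", call. = FALSE)
  invisible(image)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(what, " must have identical dimensions", call. = FALSE)
  invisible(NULL)
}

#' Separable Gaussian smoothing with replicate padding
#'
#' Convolves a matrix with a Gaussian kernel (radius `ceiling(3*sigma)`)
#' along rows then columns, replicating edge values so borders are not
#' darkened. `sigma <= 0` returns the input unchanged.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation of the kernel, in pixels.
#' @return smoothed matrix of the same shape.
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(m, rows) {
    n <- if (rows) nrow(m) else ncol(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (o in seq(-r, r)) {
      idx <- clamp(seq_len(n) + o, 1L, n)
      w <- k[o + r + 1L]
      out <- out + if (rows) w * m[idx, , drop = FALSE]
             else w * m[, idx, drop = FALSE]
    }
    out
  }
  blur_axis(blur_axis(img, TRUE), FALSE)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# central-difference gradient; returns d/drow and d/dcol with clamped borders
grad_central <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  up <- m[clamp(seq_len(nr) - 1L, 1L, nr), , drop = FALSE]
  dn <- m[clamp(seq_len(nr) + 1L, 1L, nr), , drop = FALSE]
  lf <- m[, clamp(seq_len(nc) - 1L, 1L, nc), drop = FALSE]
  rt <- m[, clamp(seq_len(nc) + 1L, 1L, nc), drop = FALSE]
  list(drow = (dn - up) / 2, dcol = (rt - lf) / 2)
}

#' Compact a label map to consecutive labels
#'
#' Remaps the non-zero labels of a label map to `1..K`, preserving their
#' numeric order; 0 stays background.
#'
#' @param labels integer matrix of non-negative labels.
#' @return integer matrix with labels forming the contiguous set `{0..K}`.
#' @export
compact_labels <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0] <- match(labels[labels > 0], u)
  out
}
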