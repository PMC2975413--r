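# iterative class-mean-midpoint (ISODATA) thresholding

#' Iterative automatic threshold
#'
#' Finds a global intensity threshold separating dark granules from the light
#' background of a bimodal micrograph. Starting from `t0` (default: the image
#' mean), pixels are split at the current threshold `T` into a dark class
#' (`< T`, mean `mu1`) and a light class (`>= T`, mean `mu2`), and `T` is
#' replaced by `(mu1 + mu2) / 2` until successive thresholds differ by less
#' than `eps`.
#'
#' A constant image cannot be split; it returns the constant with the
#' `degenerate` flag set. If a class empties mid-iteration its mean is taken
#' as the current `T`, keeping the update defined.
#'
#' @param image numeric intensity matrix in `[0, 255]`.
#' @param t0 initial threshold; defaults to `mean(image)`.
#' @param eps stopping tolerance on the threshold change (intensity units).
#' @param max_iter iteration cap.
#' @return an object of class `threshold_state`: list with `t0`, `t`, `eps`,
#'   `mu1`, `mu2`, `n_iter`, `degenerate`, `converged`.
#' @export
iterative_threshold <- function(image, t0 = NULL, eps = 0.2,
                                max_iter = 1000L) {
  assert_gray_image(image)
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  px <- as.numeric(image)
  if (is.null(t0)) t0 <- mean(px)

  if (min(px) == max(px)) {
    return(structure(list(t0 = t0, t = px[1], eps = eps, mu1 = px[1],
                          mu2 = px[1], n_iter = 0L, degenerate = TRUE,
                          converged = TRUE),
                     class = "threshold_state"))
  }

  t <- t0
  mu1 <- mu2 <- t
  n_iter <- 0L
  converged <- FALSE
  while (n_iter < max_iter) {
    c1 <- px[px < t]
    c2 <- px[px >= t]
    mu1 <- if (length(c1)) mean(c1) else t
    mu2 <- if (length(c2)) mean(c2) else t
    t_new <- (mu1 + mu2) / 2
    n_iter <- n_iter + 1L
    done <- abs(t_new - t) < eps
    t <- t_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  structure(list(t0 = t0, t = t, eps = eps, mu1 = mu1, mu2 = mu2,
                 n_iter = n_iter, degenerate = FALSE, converged = converged),
            class = "threshold_state")
}

#' @export
print.threshold_state <- function(x, ...) {
  cat(sprintf(
    "iterative threshold: T0 = %.3f -> T = %.3f (eps %.3g, %d iterations%s)\n",
    x$t0, x$t, x$eps, x$n_iter,
    if (x$degenerate) ", degenerate constant image" else ""))
  invisible(x)
}

#' Binarize an image at a converged threshold
#'
#' With the default dark-foreground polarity (granules darker than the
#' background), foreground is `pixel < T`; pixels exactly at `T` belong to
#' the background class.
#'
#' @param image numeric intensity matrix.
#' @param state a `threshold_state` from [iterative_threshold()].
#' @param polarity `"dark_foreground"` (default) or `"light_foreground"`.
#' @return logical matrix, `TRUE` = foreground granule pixels.
#' @export
binarize <- function(image, state,
                     polarity = c("dark_foreground", "light_foreground")) {
  assert_gray_image(image)
  polarity <- match.arg(polarity)
  if (!inherits(state, "threshold_state"))
    stop("state must come from iterative_threshold()", call. = FALSE)
  if (state$degenerate) {
    warning("degenerate threshold (constant image): returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  if (polarity == "dark_foreground") image < state$t else image > state$t
}
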