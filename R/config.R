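# pipeline configuration

#' Pipeline configuration
#'
#' Returns the default configuration, optionally overridden by named nested
#' lists, e.g. `seg_config(roundness = list(threshold = 0.75))`. Keys:
#'
#' * `threshold`: `t0` (`NULL` = image mean), `eps` (0.2), `polarity`
#'   (`"dark_foreground"`).
#' * `chamfer`: `weights` (`c(3, 4)`).
#' * `watershed`: `connectivity` (8; the only supported value, matching the
#'   diagonal chamfer step).
#' * `roundness`: `threshold` (0.70, useful range 0.70–0.75), `min_area` (9).
#' * `gvf`: `mu` (0.1), `max_iter` (5000), `tol` (1e-5), `sigma` (1.5).
#' * `critical`: `sim_threshold` (0.90), `min_directions` (7),
#'   `search_radius_factor` (0.75), `probe_radius` (3).
#' * `fcm`: `m` (2), `tol` (1e-4), `max_iter` (100),
#'   `weights` (`c(0.25, 0.25, 1)`).
#'
#' @param ... named overrides merged over the defaults.
#' @return object of class `seg_config`.
#' @export
seg_config <- function(...) {
  cfg <- list(
    threshold = list(t0 = NULL, eps = 0.2, polarity = "dark_foreground"),
    chamfer = list(weights = c(3L, 4L)),
    watershed = list(connectivity = 8L),
    roundness = list(threshold = 0.70, min_area = 9L),
    gvf = list(mu = 0.1, max_iter = 5000L, tol = 1e-5, sigma = 1.5),
    critical = list(sim_threshold = 0.90, min_directions = 7L,
                    search_radius_factor = 0.75, probe_radius = 3L),
    fcm = list(m = 2, tol = 1e-4, max_iter = 100L,
               weights = c(0.25, 0.25, 1.0))
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("overrides must be named", call. = FALSE)
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad))
      stop("unknown config section(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg <- utils::modifyList(cfg, ov)
  }
  validate_config(cfg)
  structure(cfg, class = "seg_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(threshold$eps > 0,
              threshold$polarity %in% c("dark_foreground", "light_foreground"),
              length(chamfer$weights) == 2L, all(chamfer$weights > 0),
              watershed$connectivity == 8L,
              roundness$threshold > 0, roundness$threshold <= 1,
              roundness$min_area >= 1,
              gvf$mu > 0, gvf$tol > 0, gvf$sigma >= 0,
              critical$sim_threshold > 0, critical$sim_threshold <= 1,
              critical$min_directions >= 1, critical$min_directions <= 8,
              critical$search_radius_factor > 0,
              critical$probe_radius >= 1,
              fcm$m > 1, fcm$tol > 0, length(fcm$weights) == 3L,
              all(fcm$weights > 0))
  })
  invisible(cfg)
}

#' Load a configuration from a YAML file
#'
#' The file may set any subset of the [seg_config()] keys; the rest keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return object of class `seg_config`.
#' @export
config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  ov <- yaml::read_yaml(path)
  do.call(seg_config, ov)
}
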