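# fuzzy c-means merging of oversegments into core segments

#' Group segments by connected foreground blob
#'
#' Merging is confined to a region of interest: one 8-connected component of
#' the foreground mask, holding every watershed segment inside it. Only
#' segments within the same blob can have come from the same granule cluster.
#'
#' @param labels watershed label matrix.
#' @param mask foreground mask; defaults to `labels > 0`.
#' @param records classified segment records (used to fill `core_labels`;
#'   may be omitted before classification).
#' @return list of `merge_group` objects: `component_id`, `member_labels`,
#'   `core_labels`, `roi_center` (`c(row, col)` blob centroid).
#' @export
build_merge_groups <- function(labels, mask = NULL, records = NULL) {
  if (is.null(mask)) mask <- labels > 0
  assert_same_shape(labels, mask, "labels and mask")
  comp <- label_components_cpp(mask)
  k <- max(comp)
  cores <- if (!is.null(records))
    records$label[records$classification == "core"] else integer()
  lapply(seq_len(k), function(id) {
    sel <- comp == id
    members <- sort(unique(labels[sel & labels > 0]))
    rows <- row(comp)[sel]
    cols <- col(comp)[sel]
    structure(list(component_id = id,
                   member_labels = members,
                   core_labels = intersect(members, cores),
                   roi_center = c(row = mean(rows), col = mean(cols))),
              class = "merge_group")
  })
}

#' Weighted feature vectors for the segments of a group
#'
#' Per member segment: mean intensity, intensity variance, and the distance
#' from the segment centroid to the ROI (blob) centre, each multiplied by its
#' weight. Applying the weights as coordinate scaling means plain Euclidean
#' distance in feature space realizes the weighted metric, keeping the
#' fuzzy c-means updates in their standard form. The default weights
#' `(0.25, 0.25, 1)` emphasize the centre distance: only adjacent segments
#' should merge.
#'
#' @param group a `merge_group`.
#' @param records segment records covering the group's members.
#' @param weights positive length-3 vector for (mean, variance, distance).
#' @return numeric matrix, one row per member label (rownames = labels).
#' @export
extract_features <- function(group, records, weights = c(0.25, 0.25, 1.0)) {
  if (length(weights) != 3L || any(weights <= 0))
    stop("weights must be three positive numbers", call. = FALSE)
  m <- match(group$member_labels, records$label)
  if (anyNA(m))
    stop("records are missing some group members", call. = FALSE)
  rec <- records[m, , drop = FALSE]
  d <- sqrt((rec$centroid_row - group$roi_center[["row"]])^2 +
            (rec$centroid_col - group$roi_center[["col"]])^2)
  x <- cbind(mean_intensity = weights[1] * rec$mean_intensity,
             intensity_variance = weights[2] * rec$intensity_variance,
             center_distance = weights[3] * d)
  rownames(x) <- rec$label
  x
}

#' Fuzzy c-means clustering
#'
#' Minimizes the fuzzy within-cluster sum of squares
#' `J = sum_ik u_ik^m d(x_k, v_i)^2` subject to memberships summing to 1 per
#' datum, by alternating the membership update
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and the centre update
#' `v_i = sum_k u_ik^m x_k / sum_k u_ik^m` until the largest centre shift
#' drops below `tol`. A datum coinciding with a centre receives full
#' membership there (shared equally if several centres coincide with it).
#'
#' @param x numeric data matrix, one row per datum.
#' @param centers initial centres, one row per cluster (`c >= 1`,
#'   `nrow(x) >= c`). Here they are the core-segment feature vectors, which
#'   ties cluster `i` to core `i` throughout.
#' @param m fuzzifier, `> 1`.
#' @param tol convergence tolerance on centre movement.
#' @param max_iter iteration cap.
#' @return object of class `fcm_result`: `memberships` (n x c, rows sum
#'   to 1), `centers`, `objective_trace` (non-increasing), `n_iter`,
#'   `converged`.
#' @export
fcm <- function(x, centers, m = 2, tol = 1e-4, max_iter = 100L) {
  x <- as.matrix(x)
  centers <- matrix(as.matrix(centers), ncol = ncol(x))
  n <- nrow(x)
  k <- nrow(centers)
  if (k < 1L) stop("need at least one cluster centre", call. = FALSE)
  if (n < k) stop("fewer data than clusters", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)

  dist2 <- function(v) {
    d2 <- matrix(0, n, k)
    for (i in seq_len(k))
      d2[, i] <- rowSums((x - matrix(v[i, ], n, ncol(x), byrow = TRUE))^2)
    d2
  }
  memberships <- function(d2) {
    u <- matrix(0, n, k)
    zero <- d2 <= 1e-24
    sing <- rowSums(zero) > 0
    if (any(sing))
      u[sing, ] <- zero[sing, , drop = FALSE] /
        rowSums(zero[sing, , drop = FALSE])
    if (any(!sing)) {
      p <- d2[!sing, , drop = FALSE]^(-1 / (m - 1))
      u[!sing, ] <- p / rowSums(p)
    }
    u
  }

  v <- centers
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d2 <- dist2(v)
    u <- memberships(d2)
    trace <- c(trace, sum(u^m * d2))
    um <- u^m
    denom <- colSums(um)
    v_new <- v
    ok <- denom > 0
    v_new[ok, ] <- (t(um) %*% x)[ok, , drop = FALSE] / denom[ok]
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(memberships = u, centers = v, objective_trace = trace,
                 n_iter = it, converged = converged),
            class = "fcm_result")
}

# 8-connected adjacency pairs between distinct labels of a label map
label_adjacency <- function(labels) {
  nr <- nrow(labels)
  nc <- ncol(labels)
  pairs <- list()
  shifts <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (s in shifts) {
    r1 <- seq_len(nr - abs(s[1]))
    c1 <- seq_len(nc - abs(s[2]))
    a <- labels[r1 + max(0, -s[1]), c1 + max(0, -s[2]), drop = FALSE]
    b <- labels[r1 + max(0, s[1]), c1 + max(0, s[2]), drop = FALSE]
    sel <- a != b & a > 0 & b > 0
    if (any(sel))
      pairs[[length(pairs) + 1L]] <-
        cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
  }
  if (length(pairs) == 0L) return(matrix(integer(), ncol = 2))
  unique(do.call(rbind, pairs))
}

#' Merge identified oversegments into core segments
#'
#' Within each merge group holding at least one core and one oversegment,
#' fuzzy c-means is run over the members' weighted features with one cluster
#' per core segment, initialized at the core feature vectors (which fixes the
#' cluster-to-core identity). Each oversegment then adopts the label of the
#' core whose cluster gives it the highest membership, subject to an
#' adjacency repair: if that core's territory (the core plus oversegments
#' already merged into it) does not touch the oversegment, the adjacent core
#' with the next-highest membership is used instead. Territories grow as
#' merges are applied, so assignment passes repeat until stable; any
#' leftover oversegment finally joins its highest-membership core. Groups
#' with oversegments but no core are left unmerged with a warning, and
#' groups without oversegments pass through unchanged.
#'
#' @param labels watershed label matrix.
#' @param groups list of `merge_group`s from [build_merge_groups()].
#' @param records fully classified segment records.
#' @param weights feature weights, see [extract_features()].
#' @param m,tol,max_iter fuzzy c-means parameters, see [fcm()].
#' @return object of class `merge_result`: `labels` (compacted merged label
#'   map), `assignments` (data frame oversegment -> core with membership),
#'   `label_origin` (data frame mapping compacted final labels to the
#'   original segment labels), `n_granules` (total core count).
#' @export
merge_oversegments <- function(labels, groups, records,
                               weights = c(0.25, 0.25, 1.0),
                               m = 2, tol = 1e-4, max_iter = 100L) {
  adj <- label_adjacency(labels)
  touches <- function(set_a, b) {
    any((adj[, 1] %in% set_a & adj[, 2] == b) |
        (adj[, 2] %in% set_a & adj[, 1] == b))
  }
  out <- labels
  assigns <- list()

  for (g in groups) {
    members <- g$member_labels
    cores <- g$core_labels
    ovs <- intersect(
      members, records$label[records$classification == "oversegment"])
    if (length(ovs) == 0L) next
    if (length(cores) == 0L) {
      warning("merge group ", g$component_id,
              " has oversegments but no core segment; left unmerged")
      next
    }
    feats <- extract_features(g, records, weights)
    init <- feats[as.character(cores), , drop = FALSE]
    res <- fcm(feats, init, m = m, tol = tol, max_iter = max_iter)
    u <- res$memberships
    rownames(u) <- rownames(feats)

    territory <- stats::setNames(lapply(cores, identity), cores)
    remaining <- ovs
    assigned <- integer(0)
    repeat {
      progress <- FALSE
      for (ov in remaining) {
        # cores ranked by membership, ties by core label
        memb <- u[as.character(ov), ]
        pref <- cores[order(-memb, cores)]
        pick <- NA_integer_
        for (co in pref) {
          if (touches(territory[[as.character(co)]], ov)) {
            pick <- co
            break
          }
        }
        if (!is.na(pick)) {
          territory[[as.character(pick)]] <-
            c(territory[[as.character(pick)]], ov)
          assigned[as.character(ov)] <- pick
          remaining <- setdiff(remaining, ov)
          progress <- TRUE
        }
      }
      if (!progress || length(remaining) == 0L) break
    }
    for (ov in remaining) {  # unreachable by adjacency: best membership wins
      memb <- u[as.character(ov), ]
      assigned[as.character(ov)] <- cores[order(-memb, cores)][1]
    }
    for (ov in names(assigned)) {
      out[labels == as.integer(ov)] <- assigned[[ov]]
      assigns[[length(assigns) + 1L]] <- data.frame(
        oversegment = as.integer(ov), core = assigned[[ov]],
        membership = u[ov, match(assigned[[ov]], cores)],
        group = g$component_id)
    }
  }

  kept <- sort(unique(out[out > 0]))
  compacted <- compact_labels(out)
  n_cores <- sum(records$classification == "core")
  structure(list(
    labels = compacted,
    assignments = if (length(assigns)) do.call(rbind, assigns)
                  else data.frame(oversegment = integer(), core = integer(),
                                  membership = numeric(), group = integer()),
    label_origin = data.frame(label = seq_along(kept), origin = kept),
    n_granules = n_cores), class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat(sprintf("merge: %d oversegments merged; %d granules (core segments)\n",
              nrow(x$assignments), x$n_granules))
  invisible(x)
}
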