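# fixtures and independent oracles used across the test files

# clean image of filled disks: dark granules on light background, with
# Beer-Lambert stacking where disks overlap (matching the scene generator)
disk_image <- function(n, centers, radii, fg = 60, bg = 180) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  cover <- matrix(0L, n, n)
  for (i in seq_len(nrow(centers))) {
    cover <- cover +
      ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radii[i]^2)
  }
  bg * (fg / bg)^cover
}

disk_mask <- function(n, center, radius) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# random blobby mask: union of a few random disks
random_blob_mask <- function(n, n_blobs = 3, rmin = 4, rmax = 12) {
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n_blobs)) {
    r <- runif(1, rmin, rmax)
    m <- m | disk_mask(n, c(runif(1, r + 1, n - r), runif(1, r + 1, n - r)), r)
  }
  m
}

# --- ISODATA oracle: literal re-iteration of the class-mean-midpoint update
#     on the histogram, independent of the package's vector implementation
isodata_oracle <- function(values, t0, eps, max_iter = 1000) {
  h <- table(values)
  lev <- as.numeric(names(h))
  cnt <- as.numeric(h)
  t <- t0
  for (i in seq_len(max_iter)) {
    lo <- lev < t
    m1 <- if (any(lo)) sum(lev[lo] * cnt[lo]) / sum(cnt[lo]) else t
    m2 <- if (any(!lo)) sum(lev[!lo] * cnt[!lo]) / sum(cnt[!lo]) else t
    t_new <- (m1 + m2) / 2
    if (abs(t_new - t) < eps) return(t_new)
    t <- t_new
  }
  t
}

# --- exact Euclidean distance-to-background oracle. The nearest background
#     pixel to any foreground pixel is 8-adjacent to the foreground (or lies
#     on the one-pixel ring just outside the image, which counts as
#     background), so searching those candidates is exhaustive.
exact_edt <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  if (nrow(fg) == 0) return(out)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  # background candidates: bg cells of the padded grid 8-adjacent to fg
  bgc <- which(!pad, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(bgc)), function(i) {
    r <- bgc[i, 1]; c <- bgc[i, 2]
    any(pad[max(1, r - 1):min(nr + 2, r + 1),
            max(1, c - 1):min(nc + 2, c + 1)])
  }, logical(1))
  bgc <- bgc[keep, , drop = FALSE] - 1  # back to image coordinates
  for (i in seq_len(nrow(fg))) {
    d2 <- (bgc[, 1] - fg[i, 1])^2 + (bgc[, 2] - fg[i, 2])^2
    out[fg[i, 1], fg[i, 2]] <- sqrt(min(d2))
  }
  out
}

# --- chamfer-graph distance oracle: Bellman-Ford style relaxation over the
#     8-neighbour graph with weights 3/4, border treated as background
chamfer_oracle <- function(mask, w_orth = 3, w_diag = 4) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  d <- ifelse(mask, Inf, 0)
  # virtual outside border: fg pixels on the edge can step off the image
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      best <- d[i, j]
      for (k in 1:8) {
        di <- c(-1, -1, -1, 0, 0, 1, 1, 1)[k]
        dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)[k]
        w <- if (di == 0 || dj == 0) w_orth else w_diag
        ni <- i + di; nj <- j + dj
        nb <- if (ni < 1 || ni > nr || nj < 1 || nj > nc) 0 else d[ni, nj]
        if (nb + w < best) best <- nb + w
      }
      if (best < d[i, j]) {
        d[i, j] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d / w_orth
}

# --- steepest-ascent flooding oracle for the watershed: every foreground
#     pixel climbs to its regional-maximum plateau of the distance map;
#     plateaus are labelled in raster order. Independent of the package's
#     priority-queue flood.
steepest_ascent_labels <- function(dist, mask) {
  nr <- nrow(dist)
  nc <- ncol(dist)
  offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  plateau_of <- matrix(NA_integer_, nr, nc)
  # label regional-max plateaus
  next_lab <- 0L
  plab <- matrix(0L, nr, nc)
  seen <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    v <- dist[i, j]
    comp <- list(c(i, j)); seen[i, j] <- TRUE; q <- 1; is_max <- TRUE
    while (q <= length(comp)) {
      p <- comp[[q]]; q <- q + 1
      for (k in 1:8) {
        ni <- p[1] + offs[k, 1]; nj <- p[2] + offs[k, 2]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc || !mask[ni, nj]) next
        if (dist[ni, nj] > v) is_max <- FALSE
        if (dist[ni, nj] == v && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          comp[[length(comp) + 1]] <- c(ni, nj)
        }
      }
    }
    if (is_max) {
      next_lab <- next_lab + 1L
      for (p in comp) plab[p[1], p[2]] <- next_lab
    }
  }
  climb <- function(i, j) {
    repeat {
      if (plab[i, j] > 0) return(plab[i, j])
      v <- dist[i, j]
      best <- c(i, j); bestv <- v
      for (k in 1:8) {
        ni <- i + offs[k, 1]; nj <- j + offs[k, 2]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc || !mask[ni, nj]) next
        if (dist[ni, nj] > bestv) {
          bestv <- dist[ni, nj]
          best <- c(ni, nj)
        }
      }
      if (bestv > v) {
        i <- best[1]; j <- best[2]
      } else {
        # interior of a non-max plateau: walk the plateau to an exit
        comp <- list(c(i, j))
        vis <- paste(i, j)
        q <- 1
        repeat {
          p <- comp[[q]]; q <- q + 1
          for (k in 1:8) {
            ni <- p[1] + offs[k, 1]; nj <- p[2] + offs[k, 2]
            if (ni < 1 || ni > nr || nj < 1 || nj > nc || !mask[ni, nj]) next
            if (dist[ni, nj] > v) return(climb(ni, nj))
            key <- paste(ni, nj)
            if (dist[ni, nj] == v && !(key %in% vis)) {
              vis <- c(vis, key)
              comp[[length(comp) + 1]] <- c(ni, nj)
            }
          }
          if (q > length(comp)) break
        }
        stop("plateau with no exit should have been a regional max")
      }
    }
  }
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if (mask[i, j]) out[i, j] <- climb(i, j)
  out
}

# smooth random field helper (not an oracle; just builds test inputs)
gaussian_blur_ref <- function(m, sigma) starchseg:::gaussian_blur(m, sigma)
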