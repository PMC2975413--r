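test_that("chamfer distances match single-step geometry", {
  # foreground pixel 4-adjacent to background: one orthogonal step
  m <- matrix(TRUE, 5, 5)
  m[3, 1] <- FALSE
  d <- chamfer_distance(m)
  expect_equal(d[3, 2], 1)
  expect_equal(d[3, 1], 0)

  # pixel whose only nearby background is diagonal
  m2 <- matrix(TRUE, 5, 5)
  m2[1, 1] <- FALSE
  d2 <- chamfer_distance(m2)
  expect_equal(d2[2, 2], 4 / 3)

  # 5x5 all-foreground: out-of-image pixels count as background, so the
  # centre is 2 steps to the border pixel plus 1 step off the image
  d3 <- chamfer_distance(matrix(TRUE, 5, 5))
  expect_equal(d3[3, 3], 3)
  expect_equal(d3[1, 1], 1)
  expect_equal(chamfer_oracle(matrix(TRUE, 5, 5))[3, 3], 3)
})

test_that("two-pass chamfer equals the chamfer-graph shortest path", {
  withr::local_seed(10)
  for (i in 1:10) {
    m <- random_blob_mask(14, n_blobs = 2, rmin = 2, rmax = 5)
    expect_equal(chamfer_distance(m), chamfer_oracle(m))
  }
})

test_that("chamfer map is 1-Lipschitz and zero exactly on background", {
  withr::local_seed(11)
  m <- random_blob_mask(40, n_blobs = 4)
  d <- chamfer_distance(m)
  expect_true(all(d[!m] == 0))
  expect_true(all(d[m] > 0))
  nr <- nrow(d)
  expect_true(all(abs(d[-1, ] - d[-nr, ]) <= 1 + 1e-12))          # vertical
  expect_true(all(abs(d[, -1] - d[, -nr]) <= 1 + 1e-12))          # horizontal
  expect_true(all(abs(d[-1, -1] - d[-nr, -nr]) <= 4 / 3 + 1e-12)) # diagonal
})

test_that("chamfer approximates exact Euclidean distance within 10%", {
  withr::local_seed(12)
  for (i in 1:10) {
    m <- random_blob_mask(64, n_blobs = 3)
    if (!any(m)) next
    d <- chamfer_distance(m)
    e <- exact_edt(m)
    rel <- abs(d[m] - e[m]) / e[m]
    expect_lt(max(rel), 0.10)
  }
})

test_that("watershed separates disjoint disks into their components", {
  m <- disk_mask(60, c(18, 18), 10) | disk_mask(60, c(45, 45), 8)
  ws <- watershed_segment(chamfer_distance(m), m)
  expect_equal(ws$n_segments, 2L)
  # labels coincide with connected components (up to label naming)
  expect_equal(length(unique(ws$labels[disk_mask(60, c(18, 18), 10)])), 1L)
  expect_equal(length(unique(ws$labels[disk_mask(60, c(45, 45), 8)])), 1L)

  m1 <- disk_mask(40, c(20, 20), 12)
  expect_equal(watershed_segment(chamfer_distance(m1), m1)$n_segments, 1L)
})

test_that("watershed output is a partition of the foreground", {
  withr::local_seed(13)
  for (i in 1:5) {
    m <- random_blob_mask(50, n_blobs = 3)
    ws <- watershed_segment(chamfer_distance(m), m)
    expect_true(all((ws$labels > 0) == m))
    if (ws$n_segments > 0)
      expect_setequal(unique(as.vector(ws$labels[m])), seq_len(ws$n_segments))
    expect_equal(ws$n_segments, nrow(ws$seeds))
  }
})

test_that("overlapping disks are cut near the neck minimum", {
  # radius-20 disks 30 px apart overlap; the neck is the midplane
  m <- disk_mask(80, c(40, 25), 20) | disk_mask(80, c(40, 55), 20)
  d <- chamfer_distance(m)
  ws <- watershed_segment(d, m)
  oracle <- steepest_ascent_labels(d, m)
  expect_equal(ws$n_segments, max(oracle))
  expect_equal(ws$n_segments, 2L)

  # boundary pixels between the two labels lie within 2 px of column 40
  lab <- ws$labels
  horiz_pairs <- which(lab[, -1] > 0 & lab[, -ncol(lab)] > 0 &
                       lab[, -1] != lab[, -ncol(lab)], arr.ind = TRUE)
  expect_gt(nrow(horiz_pairs), 0)
  expect_true(all(abs(horiz_pairs[, 2] + 0.5 - 40) <= 2))
})

test_that("empty masks give an empty segmentation", {
  m <- matrix(FALSE, 10, 10)
  ws <- watershed_segment(chamfer_distance(m), m)
  expect_equal(ws$n_segments, 0L)
  expect_true(all(ws$labels == 0))
})
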