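test_that("a constant image gives an all-zero edge map and zero field", {
  f <- edge_map(matrix(120, 30, 30))
  expect_true(all(f == 0))
  field <- compute_gvf(f, max_iter = 50)
  expect_true(all(field$u == 0))
  expect_true(all(field$v == 0))
})

test_that("a vertical step edge responds maximally along the step", {
  img <- matrix(60, 30, 30)
  img[, 16:30] <- 180
  f <- edge_map(img)
  expect_true(all(apply(f[5:25, ], 1, which.max) %in% 15:16))
})

test_that("a dark disk produces an annular edge response at its boundary", {
  img <- disk_image(81, matrix(c(41, 41), 1), 20)
  f <- edge_map(img)
  idx <- which(f > 0.5 * max(f), arr.ind = TRUE)
  rad <- sqrt((idx[, 1] - 41)^2 + (idx[, 2] - 41)^2)
  expect_true(all(abs(rad - 20) <= 2))
})

test_that("the discretized GVF energy is non-increasing", {
  withr::local_seed(30)
  for (i in 1:10) {
    f <- gaussian_blur_ref(matrix(runif(24 * 24), 24, 24), 1.2)
    f <- f / max(f)
    energies <- vapply(1:12, function(k)
      gvf_energy(compute_gvf(f, max_iter = k, tol = 0)), numeric(1))
    expect_true(all(diff(energies) <= 1e-10))
  }
})

test_that("cosine similarity follows the clamped definition", {
  expect_equal(cosine_similarity(c(1, 0), c(2, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), 0)  # clamped from -1
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), sqrt(2) / 2)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)   # zero vector rule
})

test_that("the field inside a clean disk vanishes at the centre and points
           outward around it", {
  img <- disk_image(101, matrix(c(51, 51), 1), 25)
  field <- compute_gvf(edge_map(img))
  mag <- sqrt(field$u^2 + field$v^2)
  expect_lt(mag[51, 51], 0.05 * max(mag))
  for (off in list(c(0, 4), c(4, 0), c(0, -4), c(-4, 0))) {
    fv <- c(field$u[51 + off[1], 51 + off[2]],
            field$v[51 + off[1], 51 + off[2]])
    outward <- c(off[2], off[1]) / sqrt(sum(off^2))
    expect_gt(cosine_similarity(fv, outward), 0.95)
  }
})

test_that("an isolated granule yields a critical point near its centre and a
           sliver fragment does not", {
  img <- disk_image(101, matrix(c(51, 51), 1), 25)
  mask <- img < 120
  # pretend the watershed split off the left sliver of the disk
  labels <- matrix(0L, 101, 101)
  labels[mask] <- 2L
  labels[mask & col(mask) < 32] <- 1L
  recs <- flag_by_roundness(measure_regions(labels, img))
  field <- compute_gvf(edge_map(img))

  main <- find_critical_point(field, recs[recs$label == 2, ], labels)
  expect_true(main$found)
  expect_lte(sqrt(sum((main$location - c(51, 51))^2)), 2)

  sliver <- recs[recs$label == 1, ]
  cp <- find_critical_point(field, sliver, labels)
  expect_false(cp$found)
})

test_that("critical-point search warns when the window misses the segment", {
  labels <- matrix(0L, 20, 20)
  labels[c(1, 400)] <- 1L  # two far corners: centroid far from both pixels
  rec <- data.frame(label = 1, centroid_row = 10.5, centroid_col = 10.5,
                    equivalent_diameter = 1)
  field <- compute_gvf(matrix(0, 20, 20), max_iter = 5)
  expect_warning(cp <- find_critical_point(field, rec, labels),
                 "search radius")
  expect_false(cp$found)
})

test_that("segment classification combines both criteria", {
  tab <- reference_segment_table()
  out <- classify_segment_table(tab)
  expect_equal(sort(out$label[out$classification == "core"]),
               c(2, 7, 8, 9, 10, 14, 15))
  # a round segment without a critical point is an oversegment
  expect_equal(out$classification[out$label == 12], "oversegment")
  # below-threshold roundness is final regardless of the critical point
  expect_equal(out$classification[out$label == 11], "oversegment")
})
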