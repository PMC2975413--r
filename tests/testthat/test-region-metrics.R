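test_that("a filled square is measured exactly", {
  img <- matrix(180, 20, 20)
  img[6:15, 4:13] <- 100
  labels <- matrix(0L, 20, 20)
  labels[6:15, 4:13] <- 1L
  r <- measure_regions(labels, img)
  expect_equal(r$area, 100L)
  expect_equal(r$mean_intensity, 100)
  expect_equal(r$intensity_variance, 0)
  expect_equal(r$centroid_row, 10.5)
  expect_equal(r$centroid_col, 8.5)
  # chain code of a 10x10 square: four sides of 9 orthogonal steps, each
  # weighted with the bias-corrected orthogonal step length 0.948
  expect_equal(r$perimeter, 36 * 0.948)
  expect_equal(r$roundness, 4 * pi * 100 / (36 * 0.948)^2)
  expect_equal(r$equivalent_diameter, 2 * sqrt(100 / pi))
})

test_that("single-pixel segments fall back to the unit-square perimeter", {
  labels <- matrix(0L, 5, 5)
  labels[3, 3] <- 1L
  r <- measure_regions(labels, matrix(10, 5, 5))
  expect_equal(r$area, 1L)
  expect_equal(r$perimeter, 4)
  expect_equal(r$centroid_row, 3)
  expect_equal(r$centroid_col, 3)
})

test_that("intensity statistics match brute-force per-pixel aggregation", {
  withr::local_seed(20)
  img <- matrix(runif(40 * 40, 0, 255), 40, 40)
  labels <- matrix(sample(0:2, 40 * 40, replace = TRUE), 40, 40)
  r <- measure_regions(labels, img)
  for (l in 1:2) {
    px <- img[labels == l]
    expect_equal(r$mean_intensity[r$label == l], mean(px))
    expect_equal(r$intensity_variance[r$label == l],
                 mean((px - mean(px))^2))
    expect_equal(r$area[r$label == l], length(px))
  }
})

test_that("roundness matches closed-form shapes", {
  r <- 7.3
  expect_equal(roundness(pi * r^2, 2 * pi * r), 1)            # circle
  expect_equal(roundness(4^2, 16), pi / 4)                    # square
  expect_equal(roundness(40 * 4, 2 * (40 + 4)), 0.2596, tolerance = 1e-3)
  # half-disk: rounder than the 0.70 cut, which is why roundness alone
  # cannot catch every oversegment
  half <- roundness(pi * r^2 / 2, pi * r + 2 * r)
  expect_equal(half, 2 * pi^2 / (pi + 2)^2)
  expect_gt(half, 0.70)
  # scale invariance in the continuum
  expect_equal(roundness(pi * (2 * r)^2, 2 * pi * (2 * r)), 1)
  expect_error(roundness(10, 0), "perimeter")
  expect_error(roundness(0, 10), "area")
})

test_that("digital disks of radius >= 15 score roundness in [0.90, 1.05]", {
  for (rad in c(15, 20, 28)) {
    n <- 2 * rad + 11
    labels <- matrix(0L, n, n)
    labels[disk_mask(n, c(rad + 6, rad + 6), rad)] <- 1L
    r <- measure_regions(labels, matrix(0, n, n))
    expect_gte(r$roundness, 0.90)
    expect_lte(r$roundness, 1.05)
  }
})

test_that("roundness flagging applies the strict-inequality cut", {
  recs <- data.frame(label = 1:4,
                     area = c(500L, 500L, 500L, 4L),
                     roundness = c(0.5, 0.70, 0.9, 0.95),
                     has_critical_point = "not_evaluated",
                     classification = "pending")
  out <- flag_by_roundness(recs, threshold = 0.70, min_area = 9L)
  expect_equal(out$classification,
               c("oversegment",  # below threshold
                 "pending",      # exactly at the threshold stays pending
                 "pending",
                 "oversegment")) # sub-resolution sliver
  all_round <- flag_by_roundness(transform(recs, roundness = 0.9,
                                           area = 500L))
  expect_true(all(all_round$classification == "pending"))
})

test_that("classification is exhaustive and exclusive after the pipeline", {
  sc <- generate_scene(scene_spec(n_granules = 4, seed = 99,
                                  image_size = c(240L, 240L)))
  res <- suppressWarnings(run_pipeline(sc$image))
  expect_true(all(res$records$classification %in% c("core", "oversegment")))
  expect_false(any(res$records$classification == "pending"))
})
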