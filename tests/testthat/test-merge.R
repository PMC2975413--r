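test_that("merge groups follow the connected foreground blobs", {
  # two disjoint blobs, one split into two watershed segments
  labels <- matrix(0L, 40, 40)
  labels[disk_mask(40, c(12, 12), 7)] <- 1L
  blob2 <- disk_mask(40, c(28, 24), 7) | disk_mask(40, c(28, 32), 6)
  labels[blob2 & col(labels) <= 28] <- 2L
  labels[blob2 & col(labels) > 28] <- 3L
  groups <- build_merge_groups(labels)
  expect_length(groups, 2L)
  expect_equal(groups[[1]]$member_labels, 1L)
  expect_equal(groups[[2]]$member_labels, c(2L, 3L))
  fg <- labels > 0 & !(labels %in% 1L)
  expect_equal(groups[[2]]$roi_center[["row"]],
               mean(row(labels)[labels %in% 2:3]))
})

test_that("feature extraction scales coordinates by the weights", {
  group <- structure(list(component_id = 1L, member_labels = 1L,
                          core_labels = integer(),
                          roi_center = c(row = 10, col = 10)),
                     class = "merge_group")
  records <- data.frame(label = 1L, mean_intensity = 100,
                        intensity_variance = 16,
                        centroid_row = 10, centroid_col = 20)
  x <- extract_features(group, records)  # distance to roi centre = 10
  expect_equal(as.vector(x), c(0.25 * 100, 0.25 * 16, 1.0 * 10))
  expect_error(extract_features(group, records, weights = c(0, 1, 1)),
               "positive")

  # two identical segments equidistant from the centre get identical vectors
  group2 <- structure(list(component_id = 1L, member_labels = c(1L, 2L),
                           core_labels = integer(),
                           roi_center = c(row = 10, col = 15)),
                      class = "merge_group")
  records2 <- rbind(records, transform(records, label = 2L,
                                       centroid_col = 10))
  x2 <- extract_features(group2, records2)
  expect_equal(unname(x2[1, ]), unname(x2[2, ]))
})

test_that("a sliver oversegment is absorbed into its core segment", {
  img <- disk_image(101, matrix(c(51, 51), 1), 25)
  mask <- img < 120
  labels <- matrix(0L, 101, 101)
  labels[mask] <- 2L
  labels[mask & col(mask) < 32] <- 1L
  stage <- run_merge_stage(img, labels)
  expect_equal(stage$n_granules, 1L)
  expect_equal(max(stage$merged_labels), 1L)
  # merging never changes the foreground support
  expect_identical(stage$merged_labels > 0, mask)
  expect_equal(stage$merge$assignments$oversegment, 1L)
  expect_equal(stage$merge$assignments$core, 2L)
})

test_that("label maps without oversegments pass through unchanged", {
  img <- disk_image(90, rbind(c(25, 25), c(65, 60)), c(14, 13))
  mask <- img < 120
  labels <- starchseg::compact_labels(
    matrix(as.integer(mask) * as.integer(col(mask) < 45) +
           as.integer(mask) * 2L * as.integer(col(mask) >= 45), 90, 90))
  stage <- run_merge_stage(img, labels)
  expect_equal(nrow(stage$merge$assignments), 0L)
  expect_equal(stage$n_granules, 2L)
  expect_identical(stage$merged_labels, labels)
})

test_that("groups with oversegments but no core are left unmerged", {
  # a thin bar splits into two slivers, both below the roundness cut
  img <- matrix(180, 40, 60)
  img[18:22, 6:55] <- 60
  labels <- matrix(0L, 40, 60)
  labels[18:22, 6:30] <- 1L
  labels[18:22, 31:55] <- 2L
  expect_warning(stage <- run_merge_stage(img, labels), "no core")
  expect_equal(stage$n_granules, 0L)
  # the two segments survive unmerged
  expect_equal(max(stage$merged_labels), 2L)
})

test_that("final granule count equals the number of core segments", {
  withr::local_seed(50)
  for (seed in c(3, 14)) {
    sc <- generate_scene(scene_spec(n_granules = 5, seed = seed))
    res <- suppressWarnings(run_pipeline(sc$image))
    expect_equal(res$n_granules,
                 sum(res$records$classification == "core"))
    # merging preserves the foreground partition
    expect_identical(res$merged_labels > 0, res$watershed$labels > 0)
  }
})
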