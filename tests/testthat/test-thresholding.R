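test_that("symmetric bimodal histogram is a one-step fixed point", {
  img <- matrix(c(rep(0, 100), rep(255, 100)), 10, 20)
  st <- iterative_threshold(img, t0 = 127.5)
  expect_equal(st$t, 127.5)
  expect_equal(st$n_iter, 1L)
  expect_false(st$degenerate)
})

test_that("asymmetric two-level image converges to the hand iteration", {
  # T0 = mean = 162.5; mu1 = 50, mu2 = 200 -> T = 125; stable thereafter
  img <- matrix(c(rep(50, 100), rep(200, 300)), 20, 20)
  st <- iterative_threshold(img)
  expect_equal(st$t0, 162.5)
  expect_equal(st$t, 125)
  expect_equal(st$mu1, 50)
  expect_equal(st$mu2, 200)
})

test_that("constant images are flagged degenerate", {
  st <- iterative_threshold(matrix(77, 5, 5))
  expect_true(st$degenerate)
  expect_equal(st$t, 77)
  expect_warning(mask <- binarize(matrix(77, 5, 5), st), "degenerate")
  expect_false(any(mask))
})

test_that("converged threshold is a fixed point of the update", {
  withr::local_seed(3)
  for (i in 1:10) {
    px <- c(rnorm(200, 60, 15), rnorm(300, 180, 20))
    img <- matrix(pmin(pmax(px, 0), 255), 25, 20)
    st <- iterative_threshold(img)
    mu1 <- mean(img[img < st$t])
    mu2 <- mean(img[img >= st$t])
    expect_lt(abs((mu1 + mu2) / 2 - st$t), st$eps)
    expect_true(st$mu1 <= st$t && st$t <= st$mu2)
  }
})

test_that("implementation agrees with the histogram ISODATA oracle", {
  withr::local_seed(4)
  for (i in 1:100) {
    n1 <- sample(50:300, 1)
    n2 <- sample(50:300, 1)
    vals <- c(sample(0:120, n1, replace = TRUE),
              sample(100:255, n2, replace = TRUE))
    img <- matrix(vals, nrow = 1)
    st <- iterative_threshold(img)
    expect_lt(abs(st$t - isodata_oracle(vals, mean(vals), st$eps)), st$eps)
  }
})

test_that("for disjoint bimodal supports the threshold falls in the gap", {
  withr::local_seed(5)
  for (i in 1:25) {
    a <- sample(0:60, 1); b <- a + sample(10:40, 1)
    cc <- b + sample(20:60, 1); d <- min(cc + sample(10:40, 1), 255)
    vals <- c(sample(a:b, 150, replace = TRUE),
              sample(cc:d, 250, replace = TRUE))
    st <- iterative_threshold(matrix(vals, nrow = 1))
    expect_true(st$t > b && st$t <= cc)
  }
})

test_that("binarization uses strict inequality with dark foreground", {
  img <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  st <- iterative_threshold(img, t0 = 127.5)
  mask <- binarize(img, st)
  expect_identical(mask, img < 127.5)

  # pixels exactly at T belong to the background class
  st2 <- structure(list(t = 100, degenerate = FALSE), class = "threshold_state")
  img2 <- matrix(c(99, 100, 101, 50), 2, 2)
  expect_identical(as.vector(binarize(img2, st2)),
                   c(TRUE, FALSE, FALSE, TRUE))

  # light-foreground polarity inverts the comparison
  expect_identical(as.vector(binarize(img2, st2, "light_foreground")),
                   c(FALSE, FALSE, TRUE, FALSE))
})
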