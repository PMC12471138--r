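test_that("channel_histogram counts exactly", {
  px <- array(0L, c(2, 2, 3))
  px[, , 1] <- matrix(c(0L, 255L, 0L, 7L), 2, 2)   # column-major: [0,255;0,7]
  img <- fundus_image(px, fov = matrix(TRUE, 2, 2))
  h <- channel_histogram(img, "R")
  expect_equal(h$counts[0 + 1], 2L)
  expect_equal(h$counts[7 + 1], 1L)
  expect_equal(h$counts[255 + 1], 1L)
  expect_equal(sum(h$counts), h$n_pixels)

  const <- constant_fundus(4, 5, c(10, 20, 30))
  expect_equal(channel_histogram(const, "G")$counts[20 + 1], 20L)

  set.seed(3)
  img <- random_fundus(9, 7, seed = 3)
  for (ch in c("R", "G", "B"))
    expect_equal(sum(channel_histogram(img, ch)$counts), 63L)
})

test_that("fov_only restricts the histogram support", {
  img <- random_fundus(32, 32, seed = 4)
  attr(img, "fov") <- circular_fov(32, 32)
  h <- channel_histogram(img, "R", fov_only = TRUE)
  expect_equal(h$n_pixels, sum(circular_fov(32, 32)))
})

test_that("average_histogram averages frequency histograms", {
  a <- constant_fundus(4, 4, c(10, 50, 90))
  b <- constant_fundus(4, 4, c(30, 50, 90))
  set <- group_histogram_set(list(a, b), group = "g")
  avg <- average_histogram(set, "R")
  expect_equal(avg[10 + 1], 0.5)
  expect_equal(avg[30 + 1], 0.5)
  expect_equal(sum(avg), 1)
  single <- group_histogram_set(list(a))
  expect_equal(average_histogram(single, "R"), single$frequencies[[1]]$R)
  expect_error(group_histogram_set(list()), "at least one")
})

test_that("mean of means equals pooled frequency for equal-size images", {
  imgs <- lapply(1:3, function(s) random_fundus(8, 8, seed = s))
  set <- group_histogram_set(imgs, group = "g")
  avg <- average_histogram(set, "B")
  pooled <- tabulate(unlist(lapply(imgs, function(im) im[, , 3])) + 1L, 256) /
    (3 * 64)
  expect_equal(avg, pooled)
})

test_that("mahalanobis_distance reduces to Euclidean under identity covariance", {
  xa <- rbind(c(3, 0, 4), c(3, 0, 4), c(3, 0, 4))
  xb <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  expect_equal(mahalanobis_distance(xa, xb, covariance = "identity"), 5)
})

test_that("mahalanobis_distance matches the dense-inverse oracle and its axioms", {
  set.seed(41)
  xa <- matrix(rnorm(10, 1, 1), 5, 2)
  xb <- matrix(rnorm(10, -1, 1), 5, 2)
  expect_equal(mahalanobis_distance(xa, xb), oracle_mahalanobis(xa, xb),
               tolerance = 1e-8)
  expect_equal(mahalanobis_distance(xa, xb), mahalanobis_distance(xb, xa))
  expect_equal(mahalanobis_distance(xa, xa), 0)
  # monotone in the mean separation under identity covariance
  d1 <- mahalanobis_distance(xa, xb, covariance = "identity")
  d2 <- mahalanobis_distance(xa + 5, xb - 5, covariance = "identity")
  expect_gt(d2, d1)
  expect_error(mahalanobis_distance(xa[1, , drop = FALSE], xb), ">= 2")
})

test_that("mahalanobis_separation works on rank-deficient histogram clouds", {
  imgs_a <- lapply(1:4, function(s) random_fundus(12, 12, seed = s))
  imgs_b <- lapply(1:4, function(s) {
    img <- random_fundus(12, 12, seed = 100 + s)
    px <- unclass(img); px[, , 2] <- pmin(px[, , 2] + 40L, 255L)
    fundus_image(px, fov = matrix(TRUE, 12, 12), group = "b")
  })
  sa <- group_histogram_set(imgs_a, "a")
  sb <- group_histogram_set(imgs_b, "b")
  expect_equal(mahalanobis_separation(sa, sa), 0, tolerance = 1e-7)
  d_g <- mahalanobis_separation(sa, sb, channels = "G")
  expect_gte(d_g, 0)
  d_all <- mahalanobis_separation(sa, sb, channels = c("R", "G", "B"))
  expect_gte(d_all, 0)
  d_shrunk <- mahalanobis_separation(sa, sb, channels = "G",
                                     covariance = "shrinkage")
  expect_gte(d_shrunk, 0)
})

test_that("bivariate_histogram counts joint values and marginalizes exactly", {
  px <- array(0L, c(1, 2, 3))
  px[1, 2, ] <- c(255L, 128L, 64L)
  img <- fundus_image(px, fov = matrix(TRUE, 1, 2))
  bh <- bivariate_histogram(img, "RB")
  expect_equal(bh$counts[0 + 1, 0 + 1], 1L)
  expect_equal(bh$counts[255 + 1, 64 + 1], 1L)
  expect_equal(sum(bh$counts), 2L)

  const <- constant_fundus(6, 6, c(9, 8, 7))
  bc <- bivariate_histogram(const, "RG")
  expect_equal(bc$counts[9 + 1, 8 + 1], 36L)
  expect_equal(sum(bc$counts != 0), 1L)

  img <- random_fundus(16, 16, seed = 6)
  for (pair in c("RG", "RB", "GB")) {
    b <- bivariate_histogram(img, pair)
    chs <- strsplit(pair, "")[[1]]
    expect_equal(rowSums(b$counts), channel_histogram(img, chs[1])$counts)
    expect_equal(colSums(b$counts), channel_histogram(img, chs[2])$counts)
  }
})
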