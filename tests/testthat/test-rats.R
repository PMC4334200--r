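# Brute-force oracle: the global gradient-weighted mean threshold,
# computed independently of the quadtree code path.
rats_oracle_threshold <- function(img, noise_threshold, lambda) {
  nr <- nrow(img); nc <- ncol(img)
  g <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dx <- (img[i, min(j + 1, nc)] - img[i, max(j - 1, 1)]) / 2
    dy <- (img[min(i + 1, nr), j] - img[max(i - 1, 1), j]) / 2
    g[i, j] <- max(abs(dx), abs(dy))
  }
  w <- ifelse(g > noise_threshold, g^lambda, 0)
  sum(w * img) / sum(w)
}

test_that("single-leaf threshold equals the brute-force weighted mean", {
  # 12x12 image: children would be 36 px < min_leaf_size, so one leaf
  set.seed(42)
  img <- matrix(sample(0:80, 144, replace = TRUE), 12, 12)
  p <- rats_params(noise_threshold = 10, lambda_factor = 3,
                   min_leaf_size = 100)
  out <- rats_threshold(img, p)
  oracle <- rats_oracle_threshold(img, 10, 3)
  expect_equal(unique(as.vector(out$threshold)), oracle,
               tolerance = 1e-12)
  expect_identical(out$mask, img > oracle)
})

test_that("a clean step edge thresholds strictly between the two levels", {
  img <- cbind(matrix(10, 12, 6), matrix(30, 12, 6))
  out <- rats_threshold(img, rats_params(noise_threshold = 5))
  t0 <- unique(as.vector(out$threshold))
  expect_length(t0, 1)
  expect_gt(t0, 10); expect_lt(t0, 30)
  expect_identical(out$mask, img == 30)
  # equal weights at the two edge-adjacent columns -> T is their mean,
  # for any lambda (checked at lambda = 12 as the large-lambda limit)
  out12 <- rats_threshold(img, rats_params(noise_threshold = 5,
                                           lambda_factor = 12))
  expect_equal(unique(as.vector(out12$threshold)), 20, tolerance = 1e-9)
})

test_that("constant images give no foreground and a warning flag", {
  expect_warning(out <- rats_threshold(matrix(7, 25, 25)),
                 "noise threshold")
  expect_false(out$any_valid)
  expect_identical(sum(out$mask), 0L)
  expect_true(all(is.na(out$threshold)))
})

test_that("quadtree leaves inherit the nearest valid ancestor", {
  # 30x30 image (children 15x15 = 225 px >= 100 -> one split); gradients
  # only in the upper-left quadrant
  img <- matrix(10, 30, 30)
  img[4:8, 4:8] <- 200
  out <- rats_threshold(img, rats_params(noise_threshold = 5,
                                         min_leaf_size = 100))
  # all quadrants carry a threshold (invalid ones inherit from the root)
  expect_false(any(is.na(out$threshold)))
  # foreground is exactly the bright block
  expect_identical(which(out$mask), which(img > 100))
})

test_that("count_puncta counts well-separated disks and merges touchers", {
  img <- matrix(0, 60, 60)
  centres <- list(c(10, 10), c(10, 40), c(30, 25), c(48, 12), c(48, 48))
  for (ct in centres) {
    rr <- outer((1:60 - ct[1])^2, (1:60 - ct[2])^2, "+")
    img[rr <= 9] <- 500
  }
  roi <- matrix(TRUE, 60, 60)
  p <- rats_params(noise_threshold = 10, min_leaf_size = 5000)
  expect_identical(count_puncta(img, roi, p), 5L)
  # merge two disks into a touching pair: 4-connectivity counts one
  img2 <- matrix(0, 60, 60)
  for (ct in list(c(20, 20), c(20, 26))) {
    rr <- outer((1:60 - ct[1])^2, (1:60 - ct[2])^2, "+")
    img2[rr <= 16] <- 500
  }
  expect_identical(count_puncta(img2, roi, p), 1L)
  # blank section: no foreground anywhere
  expect_identical(count_puncta(matrix(0, 30, 30), matrix(TRUE, 30, 30),
                                p), 0L)
  expect_error(count_puncta(img, matrix(FALSE, 60, 60), p), "empty")
})

test_that("rats_params rejects invalid settings", {
  expect_error(rats_params(noise_threshold = -1), "noise_threshold")
  expect_error(rats_params(lambda_factor = 0), "lambda")
  expect_error(rats_params(min_leaf_size = 2), "min_leaf_size")
})
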