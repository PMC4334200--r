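test_that("max projection matches a per-pixel loop oracle", {
  set.seed(7)
  stack <- lapply(1:3, function(i) matrix(rnorm(60), 6, 10))
  out <- max_intensity_projection(stack)
  oracle <- matrix(0, 6, 10)
  for (i in 1:6) for (j in 1:10)
    oracle[i, j] <- max(stack[[1]][i, j], stack[[2]][i, j],
                        stack[[3]][i, j])
  expect_identical(out, oracle)
  # identity on one slice; A vs A + c returns the brighter slice
  expect_identical(max_intensity_projection(stack[1]), stack[[1]])
  expect_identical(max_intensity_projection(list(stack[[1]],
                                                 stack[[1]] + 2)),
                   stack[[1]] + 2)
  expect_error(max_intensity_projection(list(matrix(0, 2, 2),
                                             matrix(0, 3, 3))), "shape")
})

test_that("MOC reproduces the worked example and its boundary cases", {
  a <- matrix(c(1, 2, 0, 0), 2, 2)
  b <- matrix(c(2, 4, 1, 0), 2, 2)
  expect_equal(manders_overlap(a, b), 10 / sqrt(105), tolerance = 1e-12)
  expect_equal(manders_overlap(a, a), 1, tolerance = 1e-12)
  disj <- matrix(c(0, 0, 3, 1), 2, 2)
  expect_equal(manders_overlap(a, disj), 0)
  expect_error(manders_overlap(a, matrix(0, 2, 2)), "zero")
})

test_that("MOC is symmetric and scale invariant", {
  set.seed(11)
  for (i in 1:5) {
    a <- matrix(runif(100), 10, 10)
    b <- matrix(runif(100), 10, 10)
    roi <- matrix(runif(100) > 0.3, 10, 10)
    expect_equal(manders_overlap(a, b, roi), manders_overlap(b, a, roi),
                 tolerance = 1e-12)
    expect_equal(manders_overlap(a * 7.3, b, roi),
                 manders_overlap(a, b * 0.2, roi), tolerance = 1e-12)
  }
})

test_that("autophagy index is the puncta/muscle area ratio", {
  m <- matrix(FALSE, 120, 120); m[11:110, 11:110] <- TRUE
  p <- matrix(FALSE, 120, 120); p[20:24, 20:34] <- TRUE  # 75 px
  expect_equal(autophagy_index(puncta_set(p), muscle_mask(m)), 0.0075)
  empty <- puncta_set(matrix(FALSE, 120, 120))
  expect_identical(autophagy_index(empty, muscle_mask(m)), 0)
})

test_that("flux ratio counts red-only over dual puncta", {
  mk <- function(centres, dim = c(80, 80)) {
    m <- matrix(FALSE, dim[1], dim[2])
    for (ct in centres) {
      rr <- outer((seq_len(dim[1]) - ct[1])^2,
                  (seq_len(dim[2]) - ct[2])^2, "+")
      m <- m | (rr <= 4)
    }
    puncta_set(m)
  }
  red6 <- mk(list(c(10, 10), c(10, 40), c(40, 10), c(40, 40), c(70, 10),
                  c(70, 40)))
  green3 <- mk(list(c(10, 10), c(10, 40), c(40, 10)))
  expect_equal(flux_ratio(green3, red6), 3 / 3)
  expect_equal(flux_ratio(red6, red6), 0)      # every red has a match
  expect_warning(r0 <- flux_ratio(green3, mk(list())), "no red")
  expect_identical(r0, 0)
  far_green <- mk(list(c(70, 70)))
  expect_warning(ri <- flux_ratio(far_green, mk(list(c(10, 10)))),
                 "infinite")
  expect_identical(ri, Inf)
})

test_that("detected flux ratio approximates f / (1 - f) on synthetic fields", {
  f <- 0.3
  cfg <- small_field_config(seed = 12, autophagy_level = 6,
                            acidified_fraction = f, puncta_min_sep = 10,
                            puncta_radius_sd = 0.3)
  sim <- simulate_field(cfg)
  mm <- segment_muscle(sim$field)
  green <- detect_puncta_granularity(sim$field, mm)
  red <- detect_puncta_granularity(sim$field, mm, channel = "red")
  r <- flux_ratio(green, red)
  truth <- sim$truth$n_acidified /
    (sim$truth$n_puncta - sim$truth$n_acidified)
  expect_lt(abs(r - truth), 0.2)
})
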