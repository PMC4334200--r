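test_that("ground truth index is exact and masks are consistent", {
  sim <- simulate_field(small_field_config(seed = 4))
  tr <- sim$truth
  expect_false(any(tr$puncta_mask & !tr$muscle_mask))
  expect_identical(tr$true_index,
                   sum(tr$puncta_mask) / sum(tr$muscle_mask))
  expect_identical(dim(sim$field$channels$gfp), dim(tr$muscle_mask))
  # actin bright inside muscle only: non-muscle intensities stay well
  # below the muscle level
  act <- sim$field$channels$actin
  expect_gt(median(act[tr$muscle_mask]), 600)
  expect_lt(quantile(act[!tr$muscle_mask], 0.99), 400)
})

test_that("manual mask arithmetic: 3 disjoint 25 px puncta in a 100x100 muscle", {
  m <- matrix(FALSE, 150, 150); m[26:125, 26:125] <- TRUE
  p <- matrix(FALSE, 150, 150)
  # three hand-drawn 25-pixel blocks (5x5), disjoint, inside the muscle
  p[30:34, 30:34] <- TRUE; p[60:64, 60:64] <- TRUE; p[90:94, 90:94] <- TRUE
  tr <- ground_truth(m, p)
  expect_identical(tr$true_index, 75 / 10000)
  expect_error(ground_truth(p, m), "contained")
})

test_that("zero autophagy level gives an empty puncta mask and index 0", {
  sim <- simulate_field(small_field_config(seed = 2, autophagy_level = 0))
  expect_identical(sum(sim$truth$puncta_mask), 0L)
  expect_identical(sim$truth$true_index, 0)
  expect_identical(sim$truth$n_puncta, 0L)
})

test_that("identical seeds reproduce bit-identical fields; seeds differ", {
  cfg <- small_field_config(seed = 9)
  a <- simulate_field(cfg)
  b <- simulate_field(cfg)
  expect_identical(a, b)
  d <- simulate_field(small_field_config(seed = 10))
  expect_false(identical(a$field$channels$gfp, d$field$channels$gfp))
})

test_that("simulation does not disturb the global RNG stream", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_field(small_field_config(seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("config invariants are enforced", {
  expect_error(field_sim_config(autophagy_level = -1), "autophagy_level")
  expect_error(field_sim_config(noise_sd = -2), "noise_sd")
  expect_error(field_sim_config(canvas_size = c(64, 64)), "canvas too small")
  expect_error(field_sim_config(actin_level = 0), "positive")
  expect_error(field_sim_config(acidified_fraction = 1.2),
               "acidified_fraction")
})

test_that("mean true index rises with the autophagy level", {
  levels <- c(0.5, 1, 2, 4)
  means <- vapply(levels, function(lv) {
    mean(vapply(1:6, function(s)
      simulate_field(small_field_config(seed = s,
                                        autophagy_level = lv))$truth$true_index,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("flux fields place the acidified fraction in red only", {
  cfg <- small_field_config(seed = 6, autophagy_level = 3,
                            acidified_fraction = 0.4)
  sim <- simulate_field(cfg)
  expect_true("red" %in% names(sim$field$channels))
  expect_gt(sim$truth$n_acidified, 0)
  expect_lt(sim$truth$n_acidified, sim$truth$n_puncta)
  # red channel covers all puncta; gfp channel lacks the acidified ones
  pk <- sim$truth$puncta_mask
  expect_gt(median(sim$field$channels$red[pk]), 1000)
})
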