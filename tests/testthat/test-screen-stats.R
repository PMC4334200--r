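test_that("ssmd_umvue evaluates the Gamma-corrected formula", {
  # independent evaluation of c(3) = Gamma(1)/Gamma(1/2) * sqrt(2/2)
  c3 <- gamma(1) / gamma(0.5) * sqrt(1)
  expect_equal(ssmd_umvue(c(1, 2, 3)), c3 * 2, tolerance = 1e-12)
  expect_equal(ssmd_umvue(c(1, 2, 3)), 1.1283792, tolerance = 1e-6)
  expect_equal(ssmd_umvue(c(-1, 0, 1)), 0)
  expect_error(ssmd_umvue(c(1, 2)), "insufficient")
  expect_error(ssmd_umvue(c(-2, -2, -2)), "-1")
})

test_that("the UMVUE is unbiased for the population SSMD (Monte Carlo)", {
  beta <- 1.3; sigma <- 2; n <- 4
  withr::with_seed(99, {
    d <- matrix(rnorm(n * 20000, beta * sigma, sigma), nrow = n)
    m <- colMeans(d)
    s <- sqrt(colMeans(d^2) * n / (n - 1) - m^2 * n / (n - 1))
    est <- umvue_constant(n) * m / s
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - beta), 3 * se)
  })
})

test_that("normalize_plate centres wells on the plate's neg-control median", {
  w <- data.frame(plate_id = "p1",
                  well = sprintf("A%02d", 1:5),
                  amplicon_id = c("n1", "n2", "n3", "s1", "s2"),
                  gene = c("lacZ", "lacZ", "lacZ", "g1", "g1"),
                  role = c(rep("neg_ctrl", 3), "sample", "sample"),
                  index = c(0.01, 0.02, 0.04, 0.02, 0.08))
  out <- suppressWarnings(normalize_plate(w))
  expect_equal(out$d[out$amplicon_id == "s1"], 0)         # at the median
  expect_equal(out$d[out$amplicon_id == "s2"], log(4))
  expect_equal(out$d[out$amplicon_id == "n2"], 0)
  # a plate whose wells all share one index has d = 0 everywhere
  w2 <- w; w2$index <- 0.05
  expect_equal(suppressWarnings(normalize_plate(w2))$d, rep(0, 5))
})

test_that("zero-index wells get the epsilon offset and plates need negs", {
  w <- data.frame(plate_id = "p1", well = sprintf("A%02d", 1:6),
                  amplicon_id = paste0("a", 1:6), gene = paste0("g", 1:6),
                  role = c(rep("neg_ctrl", 4), "sample", "sample"),
                  index = c(0.02, 0.02, 0.03, 0.05, 0, 0.04))
  expect_message(out <- normalize_plate(w), "epsilon")
  eps <- 0.02 * 1e-3
  expect_equal(out$d[out$amplicon_id == "a5"],
               log(eps) - median(log(c(0.02, 0.02, 0.03, 0.05))))
  # same table under the drop rule loses the zero well
  out2 <- normalize_plate(w, zero_rule = "drop")
  expect_false("a5" %in% out2$amplicon_id)
  # no negative controls anywhere -> hard failure
  w$role <- "sample"
  expect_error(suppressWarnings(normalize_plate(w)), "negative-control")
})

test_that("score_amplicons honours the sign contract and replicate rules", {
  cfg <- screen_sim_config(c(sup = 0.4, enh = 2.5, null = 1),
                           sigma_plate = 0.02, sigma_well = 0.05,
                           seed = 14)
  scr <- simulate_screen(cfg)
  sc <- score_amplicons(normalize_plate(scr$wells))
  expect_true(all(sc$ssmd[sc$gene == "sup"] < 0))
  expect_true(all(sc$ssmd[sc$gene == "enh"] > 0))
  expect_identical(sign(sc$ssmd), sign(sc$mean_d))
  # an amplicon on fewer than 3 plates is excluded with a message
  w <- normalize_plate(scr$wells)
  w2 <- w[!(w$amplicon_id == "sup_amp1" & w$plate_id == "plate3"), ]
  expect_message(sc2 <- score_amplicons(w2), "sup_amp1")
  expect_false("sup_amp1" %in% sc2$amplicon_id)
})

test_that("well and plate-mean aggregation agree for one-well amplicons", {
  scr <- simulate_screen(null_screen_config(seed = 31, n_genes = 5))
  w <- normalize_plate(scr$wells)
  a <- score_amplicons(w, aggregate = "wells")
  b <- score_amplicons(w, aggregate = "plate_mean")
  samp <- a$role == "sample"
  expect_equal(a$ssmd[samp], b$ssmd[match(a$amplicon_id[samp],
                                          b$amplicon_id)])
  # the control dsRNA occupies many wells: well-level scoring uses all
  expect_identical(a$n[a$amplicon_id == "lacZ"], 48L)
  expect_identical(b$n[b$amplicon_id == "lacZ"], 3L)
})

test_that("null amplicon scores are centred on zero (Monte Carlo)", {
  sc <- do.call(rbind, lapply(1:12, function(s) {
    scr <- simulate_screen(null_screen_config(seed = 100 + s,
                                              n_genes = 30))
    sc <- score_amplicons(normalize_plate(scr$wells))
    sc[sc$role == "sample", ]
  }))
  expect_gt(nrow(sc), 500)
  se <- sd(sc$ssmd) / sqrt(nrow(sc))
  expect_lt(abs(mean(sc$ssmd)), 3 * se)
  expect_lt(abs(mean(sc$ssmd > 0) - 0.5), 3 * 0.5 / sqrt(nrow(sc)))
})

test_that("compare_groups matches the pooled-variance textbook formula", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(tstat), df = 6)
  expect_equal(compare_groups(a, b), p_hand, tolerance = 1e-12)
  expect_equal(compare_groups(a, a), 1)
  expect_lt(compare_groups(c(1, 2, 3), c(101, 102, 103)), 1e-6)
  expect_error(compare_groups(c(1, 1), c(2, 2)), "variance")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
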