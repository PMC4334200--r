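mk_scores <- function(...) {
  s <- c(...)
  data.frame(amplicon_id = paste0("amp", seq_along(s)), gene = "g",
             role = "sample", ssmd = s)
}

test_that("the two-tier consolidation rules call the documented cases", {
  cases <- list(
    list(s = c(-0.7, -0.6), dir = "positive_regulator", tier = "multi"),
    list(s = c(-1.2, 0.1), dir = "positive_regulator", tier = "single"),
    list(s = c(-1.2, 0.6), dir = "none", tier = "none"),
    list(s = c(0.55, 0.8, -0.2), dir = "negative_regulator",
         tier = "multi"),
    list(s = c(-0.5, -0.5), dir = "positive_regulator", tier = "multi"),
    list(s = c(1.0, 0.2), dir = "negative_regulator", tier = "single"),
    list(s = c(-0.9, 0.3), dir = "none", tier = "none"),
    list(s = c(-1.2), dir = "positive_regulator", tier = "single"))
  for (cs in cases) {
    out <- call_genes(mk_scores(cs$s))
    expect_identical(out$direction, cs$dir)
    expect_identical(out$tier, cs$tier)
  }
})

test_that("genes qualifying multi in both directions are flagged ambiguous", {
  out <- call_genes(mk_scores(c(-0.6, -0.7, 0.8, 0.9)))
  expect_identical(out$direction, "none")
  expect_true(out$ambiguous)
})

test_that("calls are invariant to amplicon order and monotone in scores", {
  withr::with_seed(5, {
    for (i in 1:25) {
      s <- round(rnorm(sample(2:5, 1), sd = 0.8), 2)
      base <- call_genes(mk_scores(s))
      perm <- sample(seq_along(s))
      shuffled <- call_genes(mk_scores(s[perm]))
      expect_identical(base$direction, shuffled$direction)
      expect_identical(base$tier, shuffled$tier)
      # making a qualifying score more extreme never removes a hit
      if (base$tier == "multi") {
        idx <- which(abs(s) >= 0.5 & sign(s) ==
                       ifelse(base$direction == "positive_regulator",
                              -1, 1))[1]
        s2 <- s; s2[idx] <- s2[idx] * 3
        expect_identical(call_genes(mk_scores(s2))$direction,
                         base$direction)
      }
    }
  })
})

test_that("controls are excluded from gene calling by default", {
  sc <- rbind(mk_scores(c(-0.8, -0.9)),
              data.frame(amplicon_id = "Atg18", gene = "Atg18",
                         role = "pos_ctrl", ssmd = -8))
  out <- call_genes(sc)
  expect_identical(out$gene, "g")
  out2 <- call_genes(sc, exclude_controls = FALSE)
  expect_true("Atg18" %in% out2$gene)
})

test_that("the published hit lists are reproduced from the fixture", {
  dirs <- hit_directions()
  expect_identical(nrow(dirs), 72L)
  scores <- example_hit_scores()
  calls <- call_genes(scores)
  expect_identical(summarize_calls(calls),
                   c(positive_regulator = 47L, negative_regulator = 25L,
                     none = 0L))
  # tier and direction agree gene by gene with the published table
  m <- match(dirs$gene, calls$gene)
  expect_identical(calls$direction[m], dirs$direction)
  expect_identical(calls$tier[m], dirs$tier)
})

test_that("summarize_calls handles empty tables", {
  empty <- call_genes(data.frame(amplicon_id = character(0),
                                 gene = character(0),
                                 ssmd = numeric(0)))
  expect_identical(summarize_calls(empty),
                   c(positive_regulator = 0L, negative_regulator = 0L,
                     none = 0L))
})

test_that("hit thresholds validate their ordering", {
  expect_error(hit_thresholds(1, 0.5), "single_amplicon")
  expect_error(hit_thresholds(0, 0), "single_amplicon")
})
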