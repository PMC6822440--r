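gold_from <- function(means, dimension = "valence", sd = 1, n = 12) {
  gold_table(data.frame(picture = names(means), dimension = dimension,
                        mean = means, sd = sd, n = n))
}

test_that("crowd aggregation reduces to plain means in the limits", {
  set.seed(1)
  pool <- matrix(sample(1:9, 50, TRUE), 5, 10,
                 dimnames = list(paste0("p", 1:5), NULL))
  # k = full pool: grand mean regardless of runs
  agg <- aggregate_crowd(pool, k = 10, n_runs = 5, seed = 2)
  expect_equal(agg, rowMeans(pool), tolerance = 1e-12)
  # noise-free pool
  cpool <- matrix(6, 4, 8, dimnames = list(paste0("q", 1:4), NULL))
  expect_equal(unname(aggregate_crowd(cpool, 3, 10, 1)), rep(6, 4))
  # a 60-picture pool yields 60 means at the conventional k = 8
  pool60 <- make_additive_pool(60, 40, 1, 1, seed = 3)
  expect_identical(length(aggregate_crowd(pool60, 8, 30, 4)), 60L)
})

test_that("a constant shift separates agreement from consistency", {
  means <- setNames(seq(2, 8, length.out = 60), sprintf("p%02d", 1:60))
  gold <- gold_from(means)
  expect_equal(agreement_with_gold(means, gold, "valence")$estimate, 1)
  shifted <- means + 1
  ag <- agreement_with_gold(shifted, gold, "valence")
  expect_lt(ag$estimate, 1)
  cg <- cbind(shifted, means)
  expect_equal(icc_consistency(cg)$estimate, 1, tolerance = 1e-12)
  # against the brute-force oracle on random vectors
  set.seed(4)
  for (i in 1:20) {
    crowd <- setNames(runif(10, 1, 9), sprintf("r%02d", 1:10))
    g2 <- gold_from(pmin(pmax(crowd + rnorm(10, 0, 0.7), 1), 9))
    m <- cbind(crowd, g2$mean)
    expect_equal(agreement_with_gold(crowd, g2, "valence")$estimate,
                 oracle_icc_agreement(m), tolerance = 1e-10)
    # with a systematic offset added, agreement always drops below
    # consistency (between-method variance dominates the residual)
    m2 <- m; m2[, 2] <- m2[, 2] + 1.5
    expect_lte(oracle_icc_agreement(m2), icc_consistency(m2)$estimate + 1e-12)
  }
  expect_error(agreement_with_gold(c(zz = 5), gold, "valence"), "zz")
})

test_that("deviation flags select and order by absolute deviation", {
  means <- setNames(rep(5, 10), sprintf("p%02d", 1:10))
  gold <- gold_from(means)
  expect_identical(nrow(deviation_flags(means, gold, "valence")), 0L)
  means["p03"] <- 7
  fl <- deviation_flags(means, gold, "valence", threshold = 1.5)
  expect_identical(fl$picture, "p03")
  expect_equal(fl$delta, 2)
  # threshold 0 lists everything, sorted by |delta| descending
  means["p07"] <- 5.5
  fl0 <- deviation_flags(means, gold, "valence", threshold = 0)
  expect_identical(nrow(fl0), 10L)
  expect_identical(fl0$picture[1:2], c("p03", "p07"))
  # invariant to input picture ordering
  fl_rev <- deviation_flags(rev(means), gold, "valence", threshold = 0)
  expect_identical(fl_rev$delta, fl0$delta)
})

test_that("mean-shift test detects planted shifts and respects Bonferroni", {
  set.seed(9)
  base <- setNames(runif(60, 2, 8), sprintf("p%02d", 1:60))
  gold <- gold_from(base)
  # crowd identical to gold: zero-variance differences are degenerate
  expect_error(mean_shift_test(list(valence = base), gold), "degenerate")
  # planted shift of +0.5 with small noise is detected with direction
  crowd <- base + 0.5 + rnorm(60, 0, 0.3)
  res <- mean_shift_test(list(valence = crowd), gold)
  expect_lt(res$p_corrected, 0.05)
  expect_identical(res$direction, "crowd higher")
  expect_equal(res$p_corrected, res$p_raw)  # single dimension family
  # corrected >= raw with a 3-dimension family
  g3 <- do.call(rbind, lapply(SAM_DIMENSIONS, function(d) {
    data.frame(picture = names(base), dimension = d, mean = base, sd = 1, n = 10)
  }))
  gold3 <- gold_table(g3)
  crowd3 <- list(valence = base + rnorm(60, 0, 0.4),
                 arousal = base + 0.5 + rnorm(60, 0, 0.4),
                 dominance = base + rnorm(60, 0, 0.4))
  res3 <- mean_shift_test(crowd3, gold3)
  expect_true(all(res3$p_corrected >= res3$p_raw))
  expect_true(all(res3$p_corrected <= 1))
  # wilcoxon variant runs and reports its name
  resw <- mean_shift_test(list(valence = crowd), gold, test = "wilcoxon")
  expect_match(resw$test, "Wilcoxon")
})

test_that("null shifts reject at roughly the nominal rate", {
  set.seed(12)
  base <- setNames(runif(60, 2, 8), sprintf("p%02d", 1:60))
  gold <- gold_from(base)
  rej <- mean(replicate(200, {
    crowd <- base + rnorm(60, 0, 0.4)
    mean_shift_test(list(valence = crowd), gold)$p_raw < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.045)
})
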