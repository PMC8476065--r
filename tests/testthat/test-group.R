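test_that("repeated-measures ANOVA matches hand-computed mean squares", {
  tab <- matrix(c(2.1, 1.8, 2.5,
                  0.9, 0.7, 1.2,
                  0.1, -0.2, 0.4), nrow = 3)   # 3 subjects x 3 blocks
  res <- habituation_anova(tab)
  ms <- anova_ms_oracle(tab)
  expect_equal(res$F, ms$msc / ms$mse, tolerance = 1e-9)
  expect_equal(res$p, stats::pf(ms$msc / ms$mse, 2, 4, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 4)
})

test_that("degenerate and invalid habituation tables are handled", {
  same <- matrix(rep(c(1, 2, 3), 3), nrow = 3)  # blocks identical per subject
  res <- habituation_anova(same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_error(habituation_anova(matrix(c(1, NA, 2, 3), 2)), "complete")
  expect_error(habituation_anova(matrix(1:3, 1)), "two subjects")
})

test_that("habituation ANOVA has power at the published effect and holds
           its size under the null", {
  hits <- 0
  for (r in 1:40) {
    set.seed(r)
    tab <- sapply(c(2.2, 0.8, -0.2), function(m) m + stats::rnorm(5, 0, 0.3))
    if (habituation_anova(tab)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("relative difference uses the group-mean denominator", {
  same <- relative_difference(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$mean, 0)
  expect_equal(same$se, 0)

  r <- relative_difference(c(1, 1), c(2, 2))
  expect_equal(r$mean, -50)
  expect_equal(r$se, 0)

  ## exact agreement with direct formula evaluation on a random table
  set.seed(8)
  d1 <- rnorm(10, 2); dk <- rnorm(10, 1)
  r2 <- relative_difference(dk, d1)
  expect_equal(r2$values, 100 * (dk - d1) / mean(d1), tolerance = 1e-12)
  expect_error(relative_difference(c(1, 2), c(-1, 1)), "zero")
})

test_that("paired comparison reproduces textbook t, d and relative
           difference", {
  a <- matrix(rnorm(12), 6, 2); colnames(a) <- c("r1", "r2")
  same <- paired_compare(a, a)
  expect_equal(same$cohens_d, c(0, 0))
  expect_equal(same$p_paired, c(1, 1))

  b <- c(0, 0.5, 1)                       # var 0.25 -> pooled SD 0.5
  r <- paired_compare(cbind(b + 1), cbind(b))
  expect_equal(r$cohens_d, 2)
  expect_equal(r$pooled_sd, 0.5)
  expect_equal(r$rel_diff_pct, 100 * (mean(b + 1) - mean(b)) / mean(b))

  set.seed(9)
  x <- matrix(rnorm(20), 10, 2); y <- matrix(rnorm(20, 0.3), 10, 2)
  res <- paired_compare(x, y)
  for (i in 1:2) {
    d <- x[, i] - y[, i]
    t_oracle <- mean(d) / (stats::sd(d) / sqrt(10))
    p_oracle <- 2 * stats::pt(-abs(t_oracle), 9)
    expect_equal(res$p_paired[i], p_oracle, tolerance = 1e-9)
    expect_equal(res$cohens_d[i],
                 (mean(x[, i]) - mean(y[, i])) /
                   sqrt((stats::var(x[, i]) + stats::var(y[, i])) / 2),
                 tolerance = 1e-12)
  }
  expect_equal(res$q, stats::p.adjust(res$p_paired, "BH"))
  expect_error(paired_compare(cbind(1), cbind(2)), "two subjects")
})

test_that("Dice overlap satisfies its boundary cases and symmetry", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_equal(dice(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                    c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)), 0.5)
  expect_message(d0 <- dice(c(FALSE, FALSE), c(FALSE, FALSE)), "empty")
  expect_equal(d0, 1)
  expect_error(dice(array(TRUE, c(2, 2)), array(TRUE, c(2, 3))), "shape")

  set.seed(10)
  for (i in 1:10) {
    m1 <- array(runif(24) > 0.5, c(4, 3, 2))
    m2 <- array(runif(24) > 0.5, c(4, 3, 2))
    expect_equal(dice(m1, m2), dice(m2, m1))
    if (any(m1)) expect_equal(dice(m1, m1), 1)
  }
})

test_that("ICC(2,1) matches the mean-squares oracle and behaves under
           noise", {
  x <- c(3, 5, 7, 9)
  expect_equal(icc(x, x), 1)
  expect_equal(icc(c(1, 2, 3, 4), c(4, 3, 2, 1)),
               icc21_oracle(c(1, 2, 3, 4), c(4, 3, 2, 1)), tolerance = 1e-9)
  expect_lt(icc(c(1, 2, 3, 4), c(4, 3, 2, 1)), 0)

  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(icc(a, b), icc21_oracle(a, b), tolerance = 1e-9)
  }
  expect_true(is.na(icc(rep(1, 5), rep(1, 5))))
  expect_error(icc(1, 1), "two paired")

  ## variance components: between-voxel SD 1, measurement SD 0.33
  set.seed(12)
  vals <- replicate(100, {
    truth <- rnorm(50, 0, 1)
    icc(truth + rnorm(50, 0, 0.33), truth + rnorm(50, 0, 0.33))
  })
  expect_equal(mean(vals), 1 / (1 + 0.33^2), tolerance = 0.05)

  ## adding noise lowers agreement relative to duplication
  expect_lt(mean(vals), 1)

  ## consistency variant ignores a constant rater offset
  a <- rnorm(20)
  expect_equal(icc(a, a + 5, type = "ICC3_1"), 1, tolerance = 1e-9)
  expect_lt(icc(a, a + 5), 1)
})

test_that("visibility counting applies the two-standard-deviation slice
           rule", {
  uni <- matrix(5, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:4, 5:6] <- TRUE
  expect_equal(roi_visibility_count(uni, mask), 4)

  set.seed(13)
  slice <- matrix(rnorm(100, 100, 1), 10, 10)
  dark <- slice; dark[mask] <- 0                  # far below threshold
  expect_equal(roi_visibility_count(dark, mask), 0)

  ## explicit construction: 3 of 5 mask voxels above the threshold
  s2 <- matrix(rnorm(100, 100, 1), 10, 10)
  m2 <- matrix(FALSE, 10, 10); m2[1, 1:5] <- TRUE
  thr <- mean(s2) - 2 * stats::sd(s2)
  s2[1, 1:3] <- thr + 1
  s2[1, 4:5] <- thr - 1
  thr2 <- mean(s2) - 2 * stats::sd(s2)            # recompute after edits
  expect_equal(roi_visibility_count(s2, m2), sum(s2[m2] >= thr2))
  expect_error(roi_visibility_count(uni, matrix(FALSE, 10, 10)), "empty")
})

test_that("region summaries average sign-classified voxels and flag empty
           regions", {
  gs <- c(4, 4, 2)
  lab <- array(0L, gs); lab[1:2, 1, 1] <- 1L; lab[3:4, 4, 2] <- 2L
  delta <- array(2, c(gs, 3))
  resp <- structure(list(
    delta_pct = delta,
    delta_overall_pct = array(2, gs),
    tsnr = array(50, gs),
    cnr = array(1, gs), delay_s = 6), class = "block_response")
  sign_map <- array(0, gs); sign_map[1:2, 1, 1] <- 1
  amap <- structure(list(sign = sign_map), class = "activation_map")

  tab <- roi_summarize(resp, amap, lab, "positive", c("a", "b"))
  expect_equal(tab$n_active, c(2L, 0L))
  expect_equal(tab$delta_block1[1], 2)
  expect_equal(tab$delta_overall[1], 2)
  expect_equal(tab$tsnr[1], 50)
  expect_true(is.na(tab$delta_block1[2]))        # missing flag, not zero
  expect_error(roi_summarize(resp, amap, array(0L, gs), "positive"),
               "no regions")
})

test_that("scan/re-scan metrics are perfect on self-comparison", {
  run <- shared_default_run()
  rm <- retest_metrics(run$amap, run$amap, run$resp, run$resp,
                       run$sim$truth$roi_labels, run$sim$truth$roi_names)
  pos <- rm[rm$sign == "positive" & rm$n_scan > 1, ]
  expect_true(nrow(pos) >= 5)
  expect_true(all(pos$dice == 1))
  expect_true(all(abs(pos$icc_block1 - 1) < 1e-9))
})
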