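test_that("two-sample KS statistic and p-value honour the basic contracts", {
  same <- ks_two_sample(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  far <- ks_two_sample(c(1, 2, 3), c(10, 11, 12))
  expect_equal(far$statistic, 1)
  expect_equal(far$n_eff, 1.5)

  expect_error(ks_two_sample(1, c(1, 2)), "two observations")

  ## tied pooled values are evaluated at distinct points only
  expect_equal(ks_two_sample(c(1, 1, 2), c(1, 2, 2))$statistic, 1 / 3)

  ## statistic agrees with the independent library implementation
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    expect_equal(ks_two_sample(x, y, exact = FALSE)$statistic,
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)))
  }

  ## large-sample p uses the asymptotic Kolmogorov tail
  x <- rnorm(50); y <- rnorm(60)
  r <- ks_two_sample(x, y)
  expect_equal(r$method, "asymptotic")
  expect_equal(r$p.value,
               olfbold:::kolmogorov_q(sqrt(50 * 60 / 110) * r$statistic))
})

test_that("relative signal change follows the baseline rule exactly", {
  sched <- paper_schedule()
  expect_equal(delta_s_over_s(rep(100, 300), sched, block = 1), 0)
  expect_equal(delta_s_over_s(rep(100, 300), sched, block = "all"), 0)

  x <- rep(100, 300); x[sched$labels == "ON"] <- 102
  expect_equal(delta_s_over_s(x, sched, block = 1, delay_s = 0), 2.0)

  expect_error(delta_s_over_s(rep(0, 300), sched, block = 1), "baseline")

  ## noiseless habituating voxel: block ratios match the multipliers
  cfg <- tiny_cfg(sigma_thermal = 0, drift_amp = 0, resp_amp = 0,
                  h = c(1, 0.5, 0.25), rho = 1)
  sim <- simulate_bold(sched, cfg, seed = 1)
  vox <- which(sim$truth$roi_labels == 2)[1]
  idx <- arrayInd(vox, cfg$grid_shape)
  d <- vapply(1:3, function(b)
    delta_s_over_s(sim$bold$data[idx[1], idx[2], idx[3], ], sched, b,
                   delay_s = 0),
    numeric(1))
  expect_equal(d / d[1], c(1, 0.5, 0.25), tolerance = 0.02)
})

test_that("sign classification separates positive and negative activation", {
  expect_equal(classify_sign(c(1.3, -0.5, 5), c(TRUE, TRUE, FALSE)),
               c("positive", "negative", "none"))
  expect_message(out <- classify_sign(0, TRUE), "zero")
  expect_equal(out, "none")
})

test_that("tSNR and CNR are definitional", {
  z <- as.numeric(scale(rnorm(60)))        # exactly mean 0, sd 1
  x <- 100 + 2 * z
  b <- new_bold4d(array(rep(x, each = 1), c(1, 1, 1, 60)), 2)
  expect_equal(tsnr_map(b)[1, 1, 1], 50)

  cst <- new_bold4d(array(3, c(1, 1, 1, 10)), 2)
  expect_equal(tsnr_map(cst)[1, 1, 1], Inf)
  expect_error(tsnr_map(new_bold4d(array(1, c(1, 1, 1, 2)), 2)), "three")

  expect_equal(cnr_map(60, 2.2), 1.32)
  expect_equal(cnr_map(60, 0), 0)
})

test_that("noiseless strong-response phantom is mapped exactly by KS and
           GLM", {
  sched <- paper_schedule()
  cfg <- tiny_cfg(sigma_thermal = 0, drift_amp = 0, resp_amp = 0)
  sim <- simulate_bold(sched, cfg, seed = 1)
  det <- preprocess_bold(sim$bold, fwhm_mm = 0, hp_cutoff_hz = 0,
                         lp_cutoff_hz = 0)
  for (mapper in list(ks_activation_map, glm_activation_map)) {
    amap <- mapper(det, sched, effective_n = "nominal")
    expect_true(all(amap$sign[sim$truth$pos_mask] == 1))
    expect_true(all(amap$sign[sim$truth$neg_mask] == 2))
    expect_true(all(amap$sign[sim$truth$roi_labels == 0] == 0))
  }
})

test_that("negating the response field swaps positive and negative counts
           exactly", {
  sched <- paper_schedule()
  cfg <- tiny_cfg(sigma_thermal = 0, drift_amp = 0, resp_amp = 0)
  sim <- simulate_bold(sched, cfg, seed = 1)
  det <- preprocess_bold(sim$bold, fwhm_mm = 0, hp_cutoff_hz = 0,
                         lp_cutoff_hz = 0)
  amap <- ks_activation_map(det, sched, effective_n = "nominal")

  flipped <- det
  flipped$data <- 2 * cfg$baseline_intensity - det$data
  amap_f <- ks_activation_map(flipped, sched, effective_n = "nominal")
  expect_equal(sum(amap_f$sign == 1), sum(amap$sign == 2))
  expect_equal(sum(amap_f$sign == 2), sum(amap$sign == 1))
})

test_that("activation mapping on the default phantom detects every region
           and calibrates its threshold", {
  run <- shared_default_run()
  amap <- run$amap
  truth <- run$sim$truth
  expect_s3_class(amap, "activation_map")
  ## every positively responding region contributes detected voxels
  for (i in which(run$sim$truth$roi_names %in%
                    c("bulb", "piriform", "insula", "thalamus",
                      "orbitofrontal", "cingulate")))
    expect_gt(sum(amap$sign[truth$roi_labels == i] == 1), 0)
  ## q is a monotone adjustment of p
  ok <- !is.na(amap$q)
  expect_true(all(amap$q[ok] >= amap$p[ok] - 1e-12))
  expect_true(all(amap$D[ok] >= 0 & amap$D[ok] <= 1))
  ## active voxels carry a sign, inactive voxels do not
  expect_true(all(amap$sign[amap$active] != 0))
  expect_true(all(amap$sign[!amap$active] == 0))
  ## print and summary methods
  expect_output(print(amap), "Activation map")
  expect_equal(summary(amap)$active, sum(amap$active, na.rm = TRUE))
})

test_that("alpha = 1 marks every testable voxel active (threshold limit)", {
  run <- shared_default_run()
  amap <- ks_activation_map(run$det, run$sched, alpha = 1)
  expect_equal(sum(amap$active), length(amap$voxels))
})

test_that("degenerate schedules and inputs are rejected", {
  run <- shared_default_run()
  expect_error(ks_activation_map(run$det, run$sched, delay_s = -1))
  expect_error(ks_activation_map(run$det, run$sched, delay_s = 600),
               "ON and OFF")
})

test_that("block response object carries consistent per-block maps and CNR
           identity", {
  run <- shared_default_run()
  resp <- run$resp
  expect_s3_class(resp, "block_response")
  vox <- which(run$sim$bold$brain_mask & is.finite(resp$tsnr))
  expect_equal(resp$cnr[vox],
               resp$tsnr[vox] * resp$delta_pct[, , , 1][vox] / 100)
  expect_output(print(resp), "Block response")
})

test_that("paired CNR comparison uses the union of positively activated
           voxels", {
  run <- shared_default_run()
  tab <- cnr_compare(run$resp, run$resp, run$amap, run$amap,
                     run$sim$truth$roi_labels, run$sim$truth$roi_names)
  ## self-comparison: identical means on every region with a union mask
  has <- !is.na(tab$cnr_a)
  expect_true(any(has))
  expect_equal(tab$cnr_a[has], tab$cnr_b[has])
  expect_error(cnr_compare(run$resp, list(cnr = array(0, c(2, 2, 2))),
                           run$amap, run$amap,
                           run$sim$truth$roi_labels))
})
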