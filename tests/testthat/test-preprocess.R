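make_bold <- function(arr, tr = 2, mask = NULL)
  new_bold4d(arr, tr, 1.5, mask)

test_that("spatial smoothing: identity at zero, constant-preserving,
           correct kernel width", {
  set.seed(1)
  a <- array(rnorm(16 * 16 * 10 * 3), dim = c(16, 16, 10, 3))
  b <- make_bold(a)
  expect_equal(smooth_spatial(b, 0)$data, a)
  expect_error(smooth_spatial(b, -1), "non-negative")

  cst <- make_bold(array(7, dim = c(16, 16, 10, 2)))
  expect_equal(smooth_spatial(cst, 4)$data,
               array(7, dim = c(16, 16, 10, 2)), tolerance = 1e-12)

  ## impulse response: measured FWHM = 4 mm +/- half a 1.5 mm voxel
  imp <- array(0, dim = c(21, 21, 15, 1)); imp[11, 11, 8, 1] <- 1
  sm <- smooth_spatial(make_bold(imp), 4)$data[, , , 1]
  half <- max(sm) / 2
  for (prof in list(sm[, 11, 8], sm[11, , 8], sm[11, 11, ])) {
    above <- which(prof >= half)
    ## linear interpolation at the half-maximum crossings
    lo <- min(above); hi <- max(above)
    f_lo <- lo - 1 + (prof[lo - 1] - half) / (prof[lo - 1] - prof[lo])
    f_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
    width_mm <- (f_hi - f_lo) * 1.5
    expect_equal(width_mm, 4, tolerance = 0.75)
  }
})

test_that("high-pass projection removes sub-cutoff drift and passes the
           paradigm band", {
  n <- 300; tr <- 2; t <- (seq_len(n) - 1) * tr
  as_bold <- function(x) make_bold(array(rep(x, each = 4), c(2, 2, 1, n)))
  amp_after <- function(x, f) {
    out <- highpass_detrend(as_bold(x), 1 / 180)$data[1, 1, 1, ]
    ref <- sin(2 * pi * f * t)
    2 * abs(sum((out - mean(out)) * ref)) / sum(ref^2) / 2
  }
  slow <- sin(2 * pi * t / 360)
  out_slow <- highpass_detrend(as_bold(100 + 5 * slow), 1 / 180)$data[1, 1, 1, ]
  expect_lt(stats::sd(out_slow - mean(out_slow)), 0.1 * stats::sd(5 * slow))

  fast <- sin(2 * pi * 0.02 * t)
  out_fast <- highpass_detrend(as_bold(100 + 5 * fast), 1 / 180)$data[1, 1, 1, ]
  expect_equal(stats::sd(out_fast), stats::sd(5 * fast), tolerance = 0.1)

  cst <- highpass_detrend(as_bold(rep(42, n)), 1 / 180)$data[1, 1, 1, ]
  expect_equal(cst, rep(42, n), tolerance = 1e-10)
  expect_error(highpass_detrend(as_bold(rep(1, n)), 0.3), "Nyquist")

  ## arbitrary-phase slow tones are removed (quadrature pair in the basis)
  for (phi in c(0, 1, 2)) {
    x <- 100 + 5 * sin(2 * pi * t / 300 + phi)
    out <- highpass_detrend(as_bold(x), 1 / 180)$data[1, 1, 1, ]
    expect_lt(stats::sd(out), 0.05)
  }

  ## protected regressors shield stimulus-locked structure from the fit
  sched <- paper_schedule()
  prot <- protect_regressors(sched)
  resp <- prot[, 1] + 0.5 * prot[, 3]
  x <- 100 + 3 * resp + 4 * sin(2 * pi * t / 300 + 1)
  plain <- highpass_detrend(as_bold(x), 1 / 180)$data[1, 1, 1, ]
  shielded <- highpass_detrend(as_bold(x), 1 / 180,
                               protect = prot)$data[1, 1, 1, ]
  expect_lt(mean((shielded - (100 + 3 * resp))^2),
            mean((plain - (100 + 3 * resp))^2) / 5)
})

test_that("nuisance regression removes traced components and restores the
           mean", {
  n <- 150
  tr <- sin(2 * pi * 0.2 * (seq_len(n) - 1))
  x <- 100 + 3 * tr
  b <- make_bold(array(rep(x, each = 2), c(2, 1, 1, n)))
  out <- regress_nuisance(b, cbind(tr))$data[1, 1, 1, ]
  expect_equal(stats::var(out), 0, tolerance = 1e-20)
  expect_equal(mean(out), 100)

  ## all-zero traces are the identity
  expect_equal(regress_nuisance(b, cbind(rep(0, n)))$data, b$data)

  ## collinear columns are dropped with a warning
  expect_warning(regress_nuisance(b, cbind(tr, 2 * tr)), "collinear")
  expect_error(regress_nuisance(b, cbind(tr[1:10])), "one row per volume")
})

test_that("respiratory-trace regression raises voxel tSNR on the phantom", {
  sched <- build_paradigm(2, 0, 1, 60, 60, 1, 2)
  sim <- simulate_bold(sched, tiny_cfg(resp_amp = 15), seed = 11)
  no_reg <- stats::median(tsnr_map(sim$bold), na.rm = TRUE)
  reg <- stats::median(
    tsnr_map(regress_nuisance(sim$bold, sim$truth$nuisance_traces)),
    na.rm = TRUE)
  expect_gt(reg, no_reg)
})

test_that("zero-phase low-pass: passband preserved, stopband suppressed, no
           temporal shift", {
  n <- 300; tr <- 2; t <- (seq_len(n) - 1) * tr
  as_bold <- function(x) make_bold(array(rep(x, each = 2), c(2, 1, 1, n)))
  cst <- lowpass_filter(as_bold(rep(5, n)), 0.03)$data[1, 1, 1, ]
  expect_equal(cst, rep(5, n), tolerance = 1e-10)

  hi <- sin(2 * pi * 0.1 * t)
  out_hi <- lowpass_filter(as_bold(100 + hi), 0.03)$data[1, 1, 1, ]
  expect_lt(stats::sd(out_hi - 100), 0.1 * stats::sd(hi))

  lo <- sin(2 * pi * 0.005 * t)
  out_lo <- lowpass_filter(as_bold(100 + lo), 0.03)$data[1, 1, 1, ]
  expect_equal(stats::sd(out_lo - 100), stats::sd(lo), tolerance = 0.05)

  short <- make_bold(array(1, c(2, 1, 1, 10)))
  expect_error(lowpass_filter(short, 0.03), "warm-up")
  expect_error(lowpass_filter(as_bold(rep(1, n)), 0.3), "Nyquist")

  ## block response is not shifted: cross-correlation peaks at lag zero
  sched <- paper_schedule()
  resp <- response_template(sched, tiny_cfg(rho = 1))
  filt <- lowpass_filter(as_bold(100 + resp), 0.03)$data[1, 1, 1, ] - 100
  cc <- stats::ccf(filt, resp, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("preprocessing is mask-respecting and near-idempotent in the
           passband", {
  sched <- paper_schedule()
  sim <- simulate_bold(sched, tiny_cfg(), seed = 13)
  bold <- sim$bold
  outside <- !bold$brain_mask
  run <- function(b, fwhm) preprocess_bold(b, fwhm_mm = fwhm,
                                           hp_cutoff_hz = 1 / 180,
                                           lp_cutoff_hz = 0.03,
                                           traces = sim$truth$nuisance_traces)
  once <- run(bold, 4)
  for (t in c(1, 30))
    expect_equal(once$data[, , , t][outside], bold$data[, , , t][outside])
  stages <- vapply(once$preproc_log, `[[`, "", "stage")
  expect_equal(stages[1:4],
               c("smooth_spatial", "highpass_detrend", "regress_nuisance",
                 "lowpass_filter"))

  ## re-applying the temporal conditioning barely changes content well
  ## inside the passband (spatial smoothing is excluded: convolving twice
  ## widens the kernel by construction)
  twice <- run(once, 0)
  vox <- which(bold$brain_mask)
  m1 <- olfbold:::ts_matrix(once, vox)
  m2 <- olfbold:::ts_matrix(twice, vox)
  ## band between the high-pass cutoff and the low-pass transparent region
  ## (gain within 0.1% of unity, i.e. below 0.4 of the cutoff; nearer the
  ## cutoff every pass attenuates by design - that is rolloff, not drift)
  n <- nrow(m1)
  f <- (seq_len(n) - 1) / (n * 2)
  band <- f > 1 / 180 & f < 0.4 * 0.03
  p1 <- stats::mvfft(sweep(m1, 2, colMeans(m1)))[band, ]
  pd <- stats::mvfft(m2 - m1)[band, ]
  ## a ~1.7% floor remains: the zero-phase filter is exactly diagonal on
  ## the cosine drift components but exchanges a small amount with the
  ## quadrature (sine) ones, so strict idempotence is structurally
  ## unreachable with a phase-complete drift basis
  expect_lt(sqrt(sum(Mod(pd)^2) / sum(Mod(p1)^2)), 0.02)
})

test_that("order of preprocessing stages is fixed and logged", {
  sched <- build_paradigm(2, 0, 1, 60, 60, 1, 2)
  sim <- simulate_bold(sched, tiny_cfg(), seed = 14)
  out <- preprocess_bold(sim$bold, fwhm_mm = 4, hp_cutoff_hz = 1 / 180,
                         lp_cutoff_hz = 0)
  stages <- vapply(out$preproc_log, `[[`, "", "stage")
  expect_equal(stages, c("smooth_spatial", "highpass_detrend"))
  expect_error(preprocess_bold(sim$bold, hp_cutoff_hz = 0.04,
                               lp_cutoff_hz = 0.03), "exceed")
})
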