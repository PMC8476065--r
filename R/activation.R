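## ---- Kolmogorov-Smirnov two-sample machinery ----

## sup_x |ECDF1(x) - ECDF2(x)|, evaluated at the pooled sample points
## (right-continuous ECDFs; tied pooled values contribute one evaluation)
ks_statistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  o <- order(pooled)
  is_x <- o <= n1
  gap <- abs(cumsum(is_x) / n1 - cumsum(!is_x) / n2)
  ps <- pooled[o]
  distinct <- c(ps[-length(ps)] != ps[-1], TRUE)
  max(gap[distinct])
}

## two-sided tail of the asymptotic Kolmogorov distribution,
## Q(lambda) = 2 sum_k (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_q <- function(lambda) {
  vapply(lambda, function(l) {
    if (!is.finite(l)) return(NA_real_)
    if (l < 0.1) return(1)
    k <- seq_len(101)
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * l^2))))
  }, numeric(1))
}

kolmogorov_q_inv <- function(p) {
  stats::uniroot(function(l) kolmogorov_q(l) - p, c(0.1, 5),
                 tol = 1e-10)$root
}

#' Kolmogorov-Smirnov two-sample test
#'
#' The maximum absolute difference between the empirical cumulative
#' distribution functions of two samples, with a p-value either from full
#' permutation enumeration (exact; the default for pooled sizes up to 20) or
#' from the asymptotic two-sample Kolmogorov distribution with effective
#' sample size `n1 * n2 / (n1 + n2)`.
#'
#' @param x,y numeric samples (each of length at least 2).
#' @param exact logical; force (`TRUE`) or suppress (`FALSE`) exact
#'   permutation enumeration. Default: exact when `length(x) + length(y)
#'   <= 20`.
#' @return List with elements `statistic` (D), `p.value`, `method` and the
#'   effective sample size `n_eff`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(10, 11, 12))$statistic  # disjoint: D = 1
#' @export
ks_two_sample <- function(x, y, exact = NULL) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples must contain at least two observations")
  n1 <- length(x); n2 <- length(y)
  if (is.null(exact)) exact <- (n1 + n2) <= 20
  D <- ks_statistic(x, y)
  n_eff <- n1 * n2 / (n1 + n2)
  if (exact) {
    pooled <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    d_perm <- apply(combs, 2, function(idx)
      ks_statistic(pooled[idx], pooled[-idx]))
    p <- mean(d_perm >= D - 1e-12)
    method <- "exact permutation"
  } else {
    p <- kolmogorov_q(sqrt(n_eff) * D)
    method <- "asymptotic"
  }
  list(statistic = D, p.value = p, method = method, n_eff = n_eff)
}

## D for every column of a time-by-voxel matrix against ON/OFF index sets
ks_statistic_columns <- function(m, on_idx, off_idx) {
  n1 <- length(on_idx); n2 <- length(off_idx)
  sel <- c(on_idx, off_idx)
  is_on <- c(rep(TRUE, n1), rep(FALSE, n2))
  nv <- ncol(m)
  out <- numeric(nv)
  for (j in seq_len(nv)) {
    v <- m[sel, j]
    o <- order(v)
    z <- is_on[o]
    gap <- abs(cumsum(z) / n1 - cumsum(!z) / n2)
    vs <- v[o]
    distinct <- c(vs[-length(vs)] != vs[-1], TRUE)
    out[j] <- max(gap[distinct])
  }
  out
}

## circular shifts used for surrogate calibration: evenly spaced, avoiding
## small shifts (within one block) that partially realign with the paradigm
calibration_shifts <- function(n, n_shifts) {
  round(seq(0.1 * n, 0.9 * n, length.out = n_shifts))
}

## Deterministic subsample of columns used for calibration. Columns whose
## observed statistic sits in the top quintile are excluded first: truly
## responding voxels (and their smoothing halo) keep their response under
## shifted labels and would otherwise contaminate the upper tail of the
## surrogate null pool.
calibration_columns <- function(nv, n_max, observed_stat = NULL) {
  cand <- seq_len(nv)
  if (!is.null(observed_stat)) {
    keep <- observed_stat <= stats::quantile(observed_stat, 0.8,
                                             na.rm = TRUE)
    keep[is.na(keep)] <- FALSE
    cand <- cand[keep]
  }
  cand[unique(round(seq(1, length(cand),
                        length.out = min(n_max, length(cand)))))]
}

## Effective sample size fitted from circular-shift surrogates: pooled null
## D values from label shifts, upper tail quantile-matched to the
## Kolmogorov distribution. Accounts for the temporal autocorrelation the
## preprocessing filters introduce, which the nominal n1*n2/(n1+n2) ignores.
fit_effective_n <- function(m, on_idx, off_idx, n_shifts = 16,
                            max_voxels = 1500, tail_q = 0.998,
                            observed_stat = NULL) {
  n <- nrow(m)
  labs <- rep(FALSE, n); labs[on_idx] <- TRUE
  cols <- calibration_columns(ncol(m), max_voxels, observed_stat)
  d_null <- unlist(lapply(calibration_shifts(n, n_shifts), function(s) {
    shifted <- labs[((seq_len(n) - 1 - s) %% n) + 1]
    ks_statistic_columns(m[, cols, drop = FALSE], which(shifted),
                         which(!shifted))
  }))
  (kolmogorov_q_inv(1 - tail_q) /
      stats::quantile(d_null, tail_q, names = FALSE))^2
}

## ---- Activation maps ----

#' Voxelwise Kolmogorov-Smirnov activation map
#'
#' For every in-mask voxel, compares the distribution of signal intensities
#' during stimulus-on volumes against stimulus-off volumes (labels shifted by
#' the hemodynamic delay) with the two-sample Kolmogorov-Smirnov statistic,
#' converts to p-values, adjusts them across voxels by the
#' Benjamini-Hochberg procedure, and classifies significant voxels as
#' positively or negatively activated by the sign of their overall relative
#' signal change.
#'
#' With `effective_n = "calibrated"` (the default) the sample size entering
#' the asymptotic Kolmogorov distribution is fitted per dataset from
#' circular-shift surrogates, so that the p-values remain valid on
#' temporally filtered (autocorrelated) series; `"nominal"` uses the literal
#' `n_on * n_off / (n_on + n_off)` of independent samples.
#'
#' @param bold a preprocessed `bold4d`.
#' @param schedule the paradigm schedule.
#' @param alpha significance level on the adjusted p-values (default 0.01).
#' @param delay_s hemodynamic delay applied to the condition labels (s).
#' @param effective_n `"calibrated"` or `"nominal"`.
#' @param n_shifts,calib_voxels,tail_q calibration controls: number of
#'   circular label shifts, maximum voxels entering the surrogate pool, and
#'   the tail quantile matched to the Kolmogorov distribution.
#' @return An object of class `activation_map` with 3-D fields `D`, `p`,
#'   `q`, `active`, `sign` (`"positive"`/`"negative"`/`"none"`) and
#'   `delta_overall_pct`, plus the test metadata.
#' @export
ks_activation_map <- function(bold, schedule, alpha = 0.01, delay_s = 6,
                              effective_n = c("calibrated", "nominal"),
                              n_shifts = 16, calib_voxels = 1500,
                              tail_q = 0.998) {
  effective_n <- match.arg(effective_n)
  oo <- check_activation_inputs(bold, schedule, delay_s)
  vox <- oo$vox; m <- oo$m; testable <- oo$testable
  D <- rep(NA_real_, length(vox))
  D[testable] <- ks_statistic_columns(m[, testable, drop = FALSE],
                                      oo$on, oo$off)
  n_eff <- if (effective_n == "calibrated")
    fit_effective_n(m[, testable, drop = FALSE], oo$on, oo$off,
                    n_shifts, calib_voxels, tail_q,
                    observed_stat = D[testable])
  else length(oo$on) * length(oo$off) / (length(oo$on) + length(oo$off))
  p <- kolmogorov_q(sqrt(n_eff) * D)
  finish_activation_map(bold, schedule, vox, testable, D, p, alpha, delay_s,
                        method = paste0("ks-", effective_n), n_eff = n_eff,
                        stat_name = "D")
}

#' General-linear-model activation map (comparator)
#'
#' Least-squares fit, per voxel, of a non-habituating regressor (the on-off
#' boxcar convolved with a Gaussian response bump and shifted by the
#' hemodynamic delay), with a two-sided t-test on the regression
#' coefficient and Benjamini-Hochberg adjustment. Any temporal filters
#' recorded in the input's preprocessing log are applied to the regressor as
#' well. The t-statistic scale is calibrated from circular-shift surrogates
#' (`effective_n = "calibrated"`) in the same way as the KS map, so the two
#' detectors are compared at matched false-discovery-rate control.
#'
#' @inheritParams ks_activation_map
#' @param bump_fwhm_s FWHM (s) of the Gaussian bump convolved with the
#'   boxcar.
#' @return An `activation_map` (field `D` holds |t| rescaled to `[0, 1]` by
#'   `t / (1 + t)` for printing; `statistic` holds the raw t values).
#' @export
glm_activation_map <- function(bold, schedule, alpha = 0.01, delay_s = 6,
                               effective_n = c("calibrated", "nominal"),
                               bump_fwhm_s = 20, n_shifts = 16,
                               calib_voxels = 1500, tail_q = 0.998) {
  effective_n <- match.arg(effective_n)
  oo <- check_activation_inputs(bold, schedule, delay_s)
  vox <- oo$vox; m <- oo$m; testable <- oo$testable
  n <- nrow(m)

  x <- glm_boxcar_regressor(schedule, bump_fwhm_s, delay_s)
  x <- apply_temporal_log(x, bold$preproc_log, bold$tr_seconds)
  x <- x - mean(x)

  tv <- rep(NA_real_, length(vox))
  tv[testable] <- t_statistic_columns(m[, testable, drop = FALSE], x)
  df <- n - 2
  if (effective_n == "calibrated") {
    cols <- calibration_columns(sum(testable), calib_voxels,
                                observed_stat = abs(tv[testable]))
    mc <- m[, testable, drop = FALSE][, cols, drop = FALSE]
    t_null <- unlist(lapply(calibration_shifts(n, n_shifts), function(s) {
      xs <- x[((seq_len(n) - 1 - s) %% n) + 1]
      t_statistic_columns(mc, xs - mean(xs))
    }))
    kappa <- stats::quantile(abs(t_null), tail_q, names = FALSE) /
      stats::qt((1 + tail_q) / 2, df)
  } else kappa <- 1
  p <- 2 * stats::pt(-abs(tv) / kappa, df)
  out <- finish_activation_map(bold, schedule, vox, testable, tv, p, alpha,
                               delay_s,
                               method = paste0("glm-", effective_n),
                               n_eff = df / kappa^2, stat_name = "t")
  out
}

check_activation_inputs <- function(bold, schedule, delay_s) {
  stopifnot(inherits(bold, "bold4d"), inherits(schedule, "paradigm_schedule"))
  if (delay_s < 0) stop("hemodynamic delay must be non-negative")
  if (dim(bold$data)[4] != schedule$n_volumes)
    stop("number of volumes does not match the schedule")
  oo <- paradigm_on_off(schedule, delay_s)
  if (length(oo$on) == 0 || length(oo$off) == 0)
    stop("schedule must contain both ON and OFF volumes after the delay shift")
  vox <- which(bold$brain_mask)
  m <- ts_matrix(bold, vox)
  sds <- apply(m, 2, stats::sd)
  list(vox = vox, m = m, on = oo$on, off = oo$off, testable = sds > 0)
}

finish_activation_map <- function(bold, schedule, vox, testable, stat, p,
                                  alpha, delay_s, method, n_eff, stat_name) {
  q <- rep(NA_real_, length(vox))
  q[testable] <- stats::p.adjust(p[testable], method = "BH")
  ## alpha = 1 is the everything-passes limit (q values can equal 1 exactly)
  active <- !is.na(q) & (q < alpha | alpha >= 1)
  delta <- delta_columns(ts_matrix(bold, vox), schedule, delay_s,
                         blocks = "all")
  sgn <- classify_sign(delta, active)
  gs <- dim(bold$data)[1:3]
  structure(list(
    D = map_from_values(if (stat_name == "D") stat else
      abs(stat) / (1 + abs(stat)), vox, gs),
    statistic = map_from_values(stat, vox, gs),
    p = map_from_values(p, vox, gs),
    q = map_from_values(q, vox, gs),
    active = map_from_values(active, vox, gs, fill = FALSE) > 0,
    sign = map_from_values(match(sgn, c("none", "positive", "negative")) - 1,
                           vox, gs, fill = 0),
    delta_overall_pct = map_from_values(delta, vox, gs),
    alpha = alpha, delay_s = delay_s, method = method, n_eff = n_eff,
    voxels = vox
  ), class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  n_pos <- sum(x$sign == 1, na.rm = TRUE)
  n_neg <- sum(x$sign == 2, na.rm = TRUE)
  cat(sprintf("Activation map (%s, adjusted P < %g, delay %g s)\n",
              x$method, x$alpha, x$delay_s))
  cat(sprintf("  %d tested voxels: %d positive, %d negative (n_eff %.1f)\n",
              length(x$voxels), n_pos, n_neg, x$n_eff))
  invisible(x)
}

#' @export
summary.activation_map <- function(object, ...) {
  data.frame(
    voxels_tested = length(object$voxels),
    active = sum(object$active, na.rm = TRUE),
    positive = sum(object$sign == 1, na.rm = TRUE),
    negative = sum(object$sign == 2, na.rm = TRUE),
    alpha = object$alpha, method = object$method
  )
}

## boxcar (per-volume ON indicator) convolved with a Gaussian bump and
## shifted by the hemodynamic delay
glm_boxcar_regressor <- function(schedule, bump_fwhm_s = 20, delay_s = 6) {
  tr <- schedule$tr_seconds
  box <- as.numeric(schedule$labels == "ON")
  s <- bump_fwhm_s / (2 * sqrt(2 * log(2))) / tr
  half <- max(1L, ceiling(3 * s))
  k <- exp(-(-half:half)^2 / (2 * s^2)); k <- k / sum(k)
  padded <- c(rep(0, half), box, rep(0, half))
  conv <- stats::filter(padded, k, sides = 2)[(half + 1):(half +
                                                            length(box))]
  shift <- round(delay_s / tr)
  c(rep(0, shift), conv)[seq_along(box)]
}

t_statistic_columns <- function(m, x) {
  n <- nrow(m)
  xx <- sum(x^2)
  mc <- sweep(m, 2, colMeans(m))
  beta <- as.numeric(crossprod(mc, x)) / xx
  rss <- colSums(mc^2) - beta^2 * xx
  beta / sqrt(pmax(rss, 0) / (n - 2) / xx)
}

## temporal filters recorded in a preprocessing log, applied to a regressor
apply_temporal_log <- function(x, log, tr) {
  for (st in log) {
    if (st$stage == "highpass_detrend" && st$n_basis > 0) {
      B <- dct_drift_basis(length(x), st$cutoff_hz, tr)
      xc <- x - mean(x)
      x <- mean(x) + xc - B %*% qr.coef(qr(B), xc)
    } else if (st$stage == "lowpass_filter") {
      n <- length(x)
      xc <- x - mean(x)
      xp <- c(xc, rev(xc))
      np <- 2 * n
      f <- c(0:(np %/% 2), -rev(seq_len(np - np %/% 2 - 1))) / (np * tr)
      gain <- 1 / (1 + (abs(f) / st$cutoff_hz)^(2 * st$order))
      x <- mean(x) + Re(stats::fft(stats::fft(xp) * gain,
                                   inverse = TRUE))[seq_len(n)] / np
    }
  }
  as.numeric(x)
}

#' Classify activation sign
#'
#' Splits activated voxels into positively and negatively activated by the
#' sign of the overall relative signal change; voxels that are not active
#' (or active with exactly zero change, which is noted) are `"none"`.
#'
#' @param delta_overall_pct numeric vector of overall percent signal change.
#' @param active logical vector of the same length.
#' @return Character vector in `{"positive", "negative", "none"}`.
#' @export
classify_sign <- function(delta_overall_pct, active) {
  stopifnot(length(delta_overall_pct) == length(active))
  out <- rep("none", length(active))
  act <- active & !is.na(delta_overall_pct)
  out[act & delta_overall_pct > 0] <- "positive"
  out[act & delta_overall_pct < 0] <- "negative"
  if (any(act & delta_overall_pct == 0))
    message("active voxel(s) with exactly zero signal change left unclassified")
  out
}

## ---- Relative signal change, tSNR, CNR ----

## per-column percent signal change for one block ("all" pools on-blocks
## against the pooled baselines)
delta_columns <- function(m, schedule, delay_s = 6, blocks = "all") {
  win <- paradigm_windows(schedule, delay_s)
  if (identical(blocks, "all")) {
    on_idx <- unlist(win$on)
    base_idx <- unlist(win$base)
  } else {
    on_idx <- win$on[[blocks]]
    base_idx <- win$base[[blocks]]
  }
  B <- colMeans(m[base_idx, , drop = FALSE])
  S <- colMeans(m[on_idx, , drop = FALSE])
  d <- 100 * (S - B) / B
  d[B == 0] <- NA_real_
  d
}

#' Relative signal change of one voxel time course
#'
#' Percent signal change between a stimulation block and its baseline, where
#' the baseline is the mean over the second half of the stimulus-off period
#' preceding the block (the first half is excluded because the post-stimulus
#' transition can last up to a full on-period). `block = "all"` pools every
#' on-block against the pooled baselines.
#'
#' @param x numeric voxel time course.
#' @param schedule the paradigm schedule.
#' @param block integer block number or `"all"`.
#' @param delay_s hemodynamic delay shifting all sampling windows (s).
#' @return Percent signal change (scalar).
#' @examples
#' sched <- build_paradigm()
#' x <- rep(100, sched$n_volumes)
#' x[sched$labels == "ON"] <- 102
#' delta_s_over_s(x, sched, block = 1, delay_s = 0)  # 2 percent
#' @export
delta_s_over_s <- function(x, schedule, block = "all", delay_s = 6) {
  stopifnot(inherits(schedule, "paradigm_schedule"))
  if (schedule$n_blocks < 1) stop("schedule must contain at least one block")
  if (!identical(block, "all"))
    stopifnot(block >= 1, block <= schedule$n_blocks)
  d <- unname(delta_columns(cbind(x), schedule, delay_s, blocks = block))
  if (is.na(d)) stop("zero baseline: degenerate input series")
  d
}

#' Temporal signal-to-noise ratio map
#'
#' Voxelwise temporal mean divided by temporal standard deviation (n - 1
#' denominator). Constant voxels get an infinity sentinel and are excluded
#' from ROI summaries downstream.
#'
#' @param bold a `bold4d` with at least 3 volumes.
#' @return 3-D array (NA outside the brain mask).
#' @export
tsnr_map <- function(bold) {
  stopifnot(inherits(bold, "bold4d"))
  if (dim(bold$data)[4] < 3) stop("tSNR needs at least three time points")
  vox <- which(bold$brain_mask)
  m <- ts_matrix(bold, vox)
  mu <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  v <- ifelse(sds == 0, Inf, mu / sds)
  map_from_values(v, vox, dim(bold$data)[1:3])
}

#' Contrast-to-noise ratio map
#'
#' CNR defined as the product of the temporal SNR and the block-1 relative
#' signal change expressed as a fraction.
#'
#' @param tsnr 3-D tSNR array.
#' @param block1_delta_pct 3-D array of block-1 percent signal change.
#' @return 3-D CNR array.
#' @examples
#' cnr_map(60, 2.2)  # 1.32
#' @export
cnr_map <- function(tsnr, block1_delta_pct) {
  if (is.array(tsnr) && is.array(block1_delta_pct))
    stopifnot(all(dim(tsnr) == dim(block1_delta_pct)))
  tsnr * block1_delta_pct / 100
}

#' Block-wise response quantification
#'
#' Per-voxel percent signal change for each stimulation block and pooled
#' over blocks, the temporal SNR, and the CNR (tSNR times fractional block-1
#' signal change).
#'
#' @param bold a preprocessed `bold4d`.
#' @param schedule the paradigm schedule.
#' @param delay_s hemodynamic delay (s).
#' @return Object of class `block_response`: `delta_pct` (4-D array, last
#'   axis = block), `delta_overall_pct`, `tsnr`, `cnr` (3-D arrays).
#' @export
block_response <- function(bold, schedule, delay_s = 6) {
  stopifnot(inherits(bold, "bold4d"), inherits(schedule, "paradigm_schedule"))
  vox <- which(bold$brain_mask)
  m <- ts_matrix(bold, vox)
  gs <- dim(bold$data)[1:3]
  delta <- array(NA_real_, dim = c(gs, schedule$n_blocks))
  for (b in seq_len(schedule$n_blocks))
    delta[, , , b] <- map_from_values(
      delta_columns(m, schedule, delay_s, blocks = b), vox, gs)
  tsnr <- tsnr_map(bold)
  d1 <- array(delta[, , , 1], dim = gs)
  structure(list(
    delta_pct = delta,
    delta_overall_pct = map_from_values(
      delta_columns(m, schedule, delay_s, "all"), vox, gs),
    tsnr = tsnr,
    cnr = cnr_map(tsnr, d1),
    delay_s = delay_s
  ), class = "block_response")
}

#' @export
print.block_response <- function(x, ...) {
  nb <- dim(x$delta_pct)[4]
  cat(sprintf("Block response maps: %d blocks, delay %g s\n", nb, x$delay_s))
  for (b in seq_len(nb))
    cat(sprintf("  block %d median dS/S: %.3f%%\n", b,
                stats::median(x$delta_pct[, , , b], na.rm = TRUE)))
  invisible(x)
}

#' Paired CNR comparison between two acquisition conditions
#'
#' For each region, CNR values of the two conditions are averaged over the
#' union of positively activated voxels from either condition (the same
#' voxel set for both, so regions that one condition fails to detect are
#' still evaluated on the other's voxels).
#'
#' @param resp_a,resp_b [block_response()] objects for the two conditions
#'   (same grid).
#' @param act_a,act_b matching [ks_activation_map()] results.
#' @param roi_labels integer 3-D label array.
#' @param roi_names character vector naming labels `1..K`.
#' @return Data frame per region: `roi`, `n_union` (voxels in the union
#'   mask), `cnr_a`, `cnr_b` (NA when the union is empty).
#' @export
cnr_compare <- function(resp_a, resp_b, act_a, act_b, roi_labels,
                        roi_names = NULL) {
  stopifnot(all(dim(resp_a$cnr) == dim(resp_b$cnr)),
            all(dim(roi_labels) == dim(resp_a$cnr)))
  k <- max(roi_labels)
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(k))
  pos_union <- (act_a$sign == 1) | (act_b$sign == 1)
  out <- data.frame(roi = roi_names, n_union = NA_integer_,
                    cnr_a = NA_real_, cnr_b = NA_real_)
  for (i in seq_len(k)) {
    sel <- roi_labels == i & pos_union
    sel <- sel & is.finite(resp_a$cnr) & is.finite(resp_b$cnr)
    out$n_union[i] <- sum(sel)
    if (any(sel)) {
      out$cnr_a[i] <- mean(resp_a$cnr[sel])
      out$cnr_b[i] <- mean(resp_b$cnr[sel])
    }
  }
  out
}
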