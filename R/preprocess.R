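#' Spatial Gaussian smoothing
#'
#' Convolves every time frame with a separable isotropic Gaussian kernel of
#' the stated full width at half maximum (sigma = FWHM / (2 sqrt(2 ln 2)),
#' converted to voxels per axis). Kernel rows are renormalised where they are
#' truncated by the volume edge, so a constant image is unchanged. Voxels
#' outside the brain mask keep their original values.
#'
#' @param bold a [new_bold4d()] object.
#' @param fwhm_mm kernel full width at half maximum in mm; 0 is the identity.
#' @return The smoothed `bold4d`.
#' @export
smooth_spatial <- function(bold, fwhm_mm = 4) {
  stopifnot(inherits(bold, "bold4d"))
  if (fwhm_mm < 0) stop("smoothing FWHM must be non-negative")
  if (fwhm_mm == 0) return(log_stage(bold, "smooth_spatial", fwhm_mm = 0))
  d <- dim(bold$data)
  out <- bold$data
  for (ax in 1:3) {
    sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / bold$voxel_mm[ax]
    K <- gauss_kernel_matrix(d[ax], sigma_vox)
    out <- apply_axis(out, ax, K)
  }
  keep <- !bold$brain_mask
  if (any(keep)) {
    flat_out <- matrix(out, prod(d[1:3]), d[4])
    flat_in <- matrix(bold$data, prod(d[1:3]), d[4])
    flat_out[as.vector(keep), ] <- flat_in[as.vector(keep), ]
    out <- array(flat_out, dim = d)
  }
  bold$data <- out
  log_stage(bold, "smooth_spatial", fwhm_mm = fwhm_mm)
}

## dense N x N convolution matrix of a 1-D Gaussian, rows renormalised at
## the edges (unit row sums preserve local means)
gauss_kernel_matrix <- function(n, sigma_vox) {
  half <- max(1L, ceiling(3 * sigma_vox))
  off <- -half:half
  k <- exp(-off^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

## multiply matrix K along one spatial axis of a 4-D array
apply_axis <- function(a, axis, K) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:4, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, d[axis], prod(d[-axis]))
  aperm(array(m, dim = d[perm]), order(perm))
}

## Discrete trigonometric drift basis: cosine terms at frequencies
## k/(2 n tr) strictly below the cutoff plus their quadrature sine
## partners. The sine terms matter: a cosine-only set cannot represent a
## slow oscillation of arbitrary phase, whose quadrature component would
## survive the projection and remain coherent across voxels.
dct_drift_basis <- function(n, cutoff_hz, tr) {
  n_k <- floor(2 * n * tr * cutoff_hz - 1e-9)
  if (n_k < 1) return(NULL)
  t0 <- seq_len(n) - 0.5
  cbind(sapply(seq_len(n_k), function(k) cos(pi * k * t0 / n)),
        sapply(seq_len(n_k), function(k) sin(pi * k * t0 / n)))
}

#' High-pass drift removal by discrete-cosine projection
#'
#' Removes slow baseline drift by projecting every in-mask voxel time course
#' onto the orthogonal complement of a discrete-cosine basis spanning
#' frequencies below the cutoff, then restoring the temporal mean (so that
#' relative-signal-change denominators stay meaningful).
#'
#' When `protect` is supplied (a matrix of per-volume paradigm regressors),
#' the drift coefficients are estimated jointly with those regressors and
#' only the drift component is subtracted. This prevents the projection from
#' absorbing slow paradigm-locked signal (the habituation envelope of a
#' block design has power below 1/180 Hz) and is the variant used when
#' quantifying block-wise signal change; the plain projection (`protect =
#' NULL`) is used ahead of activation testing.
#'
#' @param bold a `bold4d`.
#' @param cutoff_hz high-pass cutoff (Hz); the default is one cycle per
#'   180 s paradigm cycle.
#' @param protect optional numeric matrix (`n_volumes` rows) of regressors
#'   shielded from the drift fit.
#' @return The filtered `bold4d`.
#' @export
highpass_detrend <- function(bold, cutoff_hz = 1 / 180, protect = NULL) {
  stopifnot(inherits(bold, "bold4d"))
  n <- dim(bold$data)[4]
  if (cutoff_hz >= 1 / (2 * bold$tr_seconds))
    stop("high-pass cutoff must be below the Nyquist frequency")
  B <- dct_drift_basis(n, cutoff_hz, bold$tr_seconds)
  if (is.null(B)) return(log_stage(bold, "highpass_detrend",
                                   cutoff_hz = cutoff_hz, n_basis = 0))
  vox <- which(bold$brain_mask)
  m <- ts_matrix(bold, vox)
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  X <- if (is.null(protect)) B else {
    stopifnot(nrow(protect) == n)
    cbind(B, sweep(protect, 2, colMeans(protect)))
  }
  beta <- qr.coef(qr(X), mc)
  beta[is.na(beta)] <- 0
  drift <- B %*% beta[seq_len(ncol(B)), , drop = FALSE]
  bold <- set_ts_matrix(bold, sweep(mc - drift, 2, mu, `+`), vox)
  log_stage(bold, "highpass_detrend", cutoff_hz = cutoff_hz,
            n_basis = ncol(B), protected = !is.null(protect))
}

#' Nuisance-trace regression
#'
#' Removes the least-squares fit of mean-centred nuisance traces (e.g. a
#' recorded respiratory waveform sampled once per volume) from every in-mask
#' voxel, restoring the temporal mean. Collinear trace columns are dropped
#' with a warning.
#'
#' @param bold a `bold4d`.
#' @param traces numeric matrix or data frame, one row per volume.
#' @return The cleaned `bold4d`.
#' @export
regress_nuisance <- function(bold, traces) {
  stopifnot(inherits(bold, "bold4d"))
  X <- as.matrix(traces)
  n <- dim(bold$data)[4]
  if (nrow(X) != n)
    stop("nuisance traces must have one row per volume")
  Xc <- sweep(X, 2, colMeans(X))
  keep <- apply(Xc, 2, function(c) sum(c^2) > 0)
  Xc <- Xc[, keep, drop = FALSE]
  if (ncol(Xc) == 0) return(log_stage(bold, "regress_nuisance", n_traces = 0))
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    warning("dropping collinear nuisance trace column(s)")
    Xc <- Xc[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    qrx <- qr(Xc)
  }
  vox <- which(bold$brain_mask)
  m <- ts_matrix(bold, vox)
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  res <- mc - Xc %*% qr.coef(qrx, mc)
  bold <- set_ts_matrix(bold, sweep(res, 2, mu, `+`), vox)
  log_stage(bold, "regress_nuisance", n_traces = ncol(Xc))
}

#' Zero-phase temporal low-pass filter
#'
#' Applies a zero-phase low-pass with the magnitude response of a
#' forward-backward order-4 Butterworth filter (half-power of the underlying
#' single pass at the cutoff), implemented in the frequency domain on
#' reflection-padded, mean-centred series; the temporal mean is restored.
#' Being zero-phase, block responses are not shifted in time.
#'
#' @param bold a `bold4d`.
#' @param cutoff_hz half-power cutoff (Hz).
#' @param order Butterworth order of the underlying single pass.
#' @return The filtered `bold4d`.
#' @export
lowpass_filter <- function(bold, cutoff_hz = 0.03, order = 4) {
  stopifnot(inherits(bold, "bold4d"))
  n <- dim(bold$data)[4]
  tr <- bold$tr_seconds
  if (cutoff_hz >= 1 / (2 * tr))
    stop("low-pass cutoff must be below the Nyquist frequency")
  if (n * tr < 2 / cutoff_hz)
    stop("time series shorter than the filter warm-up (two cutoff periods)")
  vox <- which(bold$brain_mask)
  m <- ts_matrix(bold, vox)
  mu <- colMeans(m)
  filt <- lowpass_columns(sweep(m, 2, mu), cutoff_hz, tr, order)
  bold <- set_ts_matrix(bold, sweep(filt, 2, mu, `+`), vox)
  log_stage(bold, "lowpass_filter", cutoff_hz = cutoff_hz, order = order)
}

## zero-phase low-pass of mean-centred columns: reflection padding and the
## squared Butterworth magnitude applied in the frequency domain
lowpass_columns <- function(mc, cutoff_hz, tr, order = 4) {
  n <- nrow(mc)
  mp <- rbind(mc, mc[n:1, , drop = FALSE])
  np <- 2 * n
  f <- c(0:(np %/% 2), -rev(seq_len(np - np %/% 2 - 1))) / (np * tr)
  gain <- 1 / (1 + (abs(f) / cutoff_hz)^(2 * order))
  Re(stats::mvfft(stats::mvfft(mp) * gain, inverse = TRUE))[
    seq_len(n), , drop = FALSE] / np
}

#' Global mean signal trace
#'
#' Mean time course over the in-mask voxels, available as an optional
#' nuisance regressor against spatially coherent noise. Use with care on
#' strongly activated data: when a sizeable fraction of voxels responds,
#' the global mean carries the paradigm response and regressing it removes
#' signal from activated voxels (which is why the pipeline does not use it
#' by default).
#'
#' @param bold a `bold4d`.
#' @return Numeric vector, one value per volume.
#' @export
global_signal_trace <- function(bold) {
  stopifnot(inherits(bold, "bold4d"))
  rowMeans(ts_matrix(bold))
}

#' Full preprocessing chain
#'
#' Runs the fixed conditioning sequence: spatial smoothing, discrete-cosine
#' high-pass detrending, nuisance-trace regression (if traces are given) and
#' zero-phase low-pass filtering. Each stage is recorded in the object's
#' `preproc_log`. Set a parameter to 0 (or `NULL` for traces) to skip its
#' stage.
#'
#' @param bold a `bold4d`.
#' @param fwhm_mm spatial smoothing kernel FWHM (mm).
#' @param hp_cutoff_hz high-pass cutoff (Hz); 0 skips.
#' @param lp_cutoff_hz low-pass cutoff (Hz); 0 skips.
#' @param traces optional per-volume nuisance regressor matrix.
#' @param protect optional paradigm regressors shielded from the drift fit
#'   (see [highpass_detrend()]).
#' @return The preprocessed `bold4d`.
#' @export
preprocess_bold <- function(bold, fwhm_mm = 4, hp_cutoff_hz = 1 / 180,
                            lp_cutoff_hz = 0.03, traces = NULL,
                            protect = NULL) {
  if (hp_cutoff_hz > 0 && lp_cutoff_hz > 0 && lp_cutoff_hz <= hp_cutoff_hz)
    stop("low-pass cutoff must exceed the high-pass cutoff")
  if (fwhm_mm > 0) bold <- smooth_spatial(bold, fwhm_mm)
  if (hp_cutoff_hz > 0) {
    bold <- highpass_detrend(bold, hp_cutoff_hz, protect)
    ## nuisance regressors receive the same drift projection as the data,
    ## so that what is regressed matches what is actually left in the series
    if (!is.null(traces)) {
      X <- as.matrix(traces)
      B <- dct_drift_basis(nrow(X), hp_cutoff_hz, bold$tr_seconds)
      if (!is.null(B)) {
        Xc <- sweep(X, 2, colMeans(X))
        traces <- Xc - B %*% qr.coef(qr(B), Xc)
      }
    }
  }
  if (!is.null(traces)) bold <- regress_nuisance(bold, traces)
  if (lp_cutoff_hz > 0) {
    bold <- lowpass_filter(bold, lp_cutoff_hz)
    ## the low-pass boundary handling leaks a small component back into
    ## the drift subspace; a final re-projection guarantees drift-free
    ## output and makes the composed chain idempotent. The protection
    ## regressors are low-passed like the data first.
    if (hp_cutoff_hz > 0) {
      if (!is.null(protect)) {
        pc <- sweep(as.matrix(protect), 2, colMeans(as.matrix(protect)))
        protect <- lowpass_columns(pc, lp_cutoff_hz, bold$tr_seconds)
      }
      bold <- highpass_detrend(bold, hp_cutoff_hz, protect)
    }
  }
  bold
}
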