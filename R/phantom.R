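#' Configuration for the synthetic BOLD phantom
#'
#' Bundles the signal, noise and geometry parameters of the synthetic 4-D
#' BOLD phantom. The defaults emulate the phenomenology of a pulsed olfactory
#' block paradigm at high field: positive voxels respond with a bi-phasic
#' within-block time course (two smooth peaks; the second one suppressed in a
#' small olfactory-bulb-like region) whose amplitude habituates strongly
#' across the three blocks; a smaller population of voxels deactivates with
#' weak habituation; slow scanner drift, a respiratory oscillation and white
#' thermal noise are superimposed; and a static susceptibility-dropout field
#' distinguishes an EPI-like acquisition from a T2-preparation-like one.
#'
#' Within stimulation block `b` the fractional response of a positive voxel is
#' `a1 * h[b] * (g(t; t1, w) + rho * g(t; t2, w)) / m_b`, where `g` is a
#' Gaussian bump of full width at half maximum `w_s` and `m_b` normalises the
#' shape so that its mean over the on-block sampling window is 1 - hence the
#' measured block-`b` relative signal change of a noiseless voxel equals
#' `a1 * h[b]`. After the end of each block the response decays exponentially
#' with time constant `tau_trans_s` (the post-stimulus transition). Negative
#' voxels use the same timing with amplitude `-a_neg` and multipliers `h_neg`.
#'
#' @param grid_shape integer 3-vector, voxel grid dimensions.
#' @param voxel_mm isotropic voxel size in mm.
#' @param roi_layout data frame describing the regions that carry signal; see
#'   [default_roi_layout()].
#' @param a1 block-1 fractional response amplitude of positive voxels
#'   (0.022 = 2.2 percent, an olfactory-bulb-scale response).
#' @param h habituation multipliers per block (`h[1]` must be 1).
#' @param rho second-peak ratio in `[0, 1]` for generic cortical voxels;
#'   ROI-specific values in `roi_layout` override it.
#' @param t1_s,t2_s within-block peak centres (s after block onset).
#' @param w_s full width at half maximum of each response peak (s).
#' @param tau_trans_s post-stimulus transition decay time constant (s).
#' @param a_neg fractional amplitude of negative voxels (applied with a
#'   minus sign).
#' @param h_neg per-block multipliers for negative voxels.
#' @param baseline_intensity mean signal in arbitrary scanner units.
#' @param sigma_thermal SD of white thermal noise (same units; the default
#'   gives a temporal SNR of 60 at full baseline intensity).
#' @param drift_amp,drift_period_s amplitude (units) and period (s) of the
#'   sinusoidal slow drift.
#' @param resp_amp,resp_freq_hz amplitude (units) and frequency (Hz) of the
#'   respiratory oscillation (sampled at the TR, hence aliased, as in vivo).
#' @param dropout `"none"`, `"t2prep"`, `"epi"`, or a 3-D array in `[0, 1]`:
#'   multiplicative signal-attenuation field. `"epi"` attenuates the region
#'   around the bulb-like ROI to 0.05; `"t2prep"` leaves it intact.
#' @param seed integer seed making the simulation reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(grid_shape = c(40L, 40L, 24L), voxel_mm = 1.5,
                       roi_layout = default_roi_layout(grid_shape),
                       a1 = 0.022, h = c(1, 0.35, 0.15), rho = 1,
                       t1_s = 15, t2_s = 45, w_s = 20, tau_trans_s = 20,
                       a_neg = 0.005, h_neg = c(1, 1, 0.8),
                       baseline_intensity = 1000,
                       sigma_thermal = 1000 / 60,
                       drift_amp = 10, drift_period_s = 300,
                       resp_amp = 5, resp_freq_hz = 0.3,
                       dropout = "t2prep", seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), voxel_mm > 0,
            h[1] == 1, h_neg[1] == 1, all(is.finite(c(a1, a_neg, h, h_neg))),
            rho >= 0, rho <= 1, w_s > 0, baseline_intensity > 0,
            sigma_thermal >= 0, a_neg >= 0)
  if (tau_trans_s <= 0)
    stop("post-stimulus transition time constant must be positive")
  if (is.character(dropout))
    dropout <- match.arg(dropout, c("none", "t2prep", "epi"))
  else {
    stopifnot(is.array(dropout), all(dim(dropout) == grid_shape))
    if (any(dropout < 0 | dropout > 1))
      stop("dropout attenuation values must lie in [0, 1]")
  }
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
    roi_layout = roi_layout, a1 = a1, h = h, rho = rho,
    t1_s = t1_s, t2_s = t2_s, w_s = w_s, tau_trans_s = tau_trans_s,
    a_neg = a_neg, h_neg = h_neg,
    baseline_intensity = baseline_intensity, sigma_thermal = sigma_thermal,
    drift_amp = drift_amp, drift_period_s = drift_period_s,
    resp_amp = resp_amp, resp_freq_hz = resp_freq_hz,
    dropout = dropout, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default region layout of the phantom
#'
#' Eight regions on the default 40 x 40 x 24 grid: a small spherical
#' olfactory-bulb-like region placed anterior-inferiorly next to the
#' susceptibility-dropout zone (second response peak suppressed, `rho` 0.2),
#' five positively responding cuboid regions standing in for cortical and
#' subcortical olfactory areas, and two negatively responding regions. Sizes
#' and positions scale with the grid.
#'
#' @param grid_shape integer 3-vector of voxel grid dimensions.
#' @return A data frame with one row per region: `name`, `shape`
#'   (`"sphere"`/`"cuboid"`), centre voxel `cx, cy, cz`, `size` (radius in
#'   voxels for spheres; half-widths `sx, sy, sz` for cuboids), `sign`
#'   (+1/-1) and `rho`.
#' @export
default_roi_layout <- function(grid_shape = c(40L, 40L, 24L)) {
  g <- grid_shape / c(40, 40, 24)            # scale factors vs reference grid
  ## region volumes mirror the study proportions: one ~15-voxel bulb, larger
  ## cortical/subcortical regions (tens to hundreds of voxels), activated
  ## tissue ~7 percent of the brain mask
  rois <- data.frame(
    name  = c("bulb", "piriform", "insula", "thalamus", "orbitofrontal",
              "cingulate", "neg_frontal", "neg_parietal"),
    shape = c("sphere", rep("cuboid", 7)),
    cx = round(c(20, 13, 28, 20, 20, 20, 27, 12) * g[1]),
    cy = round(c(8, 25, 25, 20, 13, 28, 14, 18) * g[2]),
    cz = round(c(7, 12, 12, 12, 9, 18, 14, 16) * g[3]),
    sx = c(1.75, 3, 3, 2, 3, 3, 2, 2),
    sy = c(1.75, 3, 3, 2, 2, 2, 2, 2),
    sz = c(1.75, 2, 2, 2, 2, 1, 1, 1),
    sign = c(1, 1, 1, 1, 1, 1, -1, -1),
    rho  = c(0.2, 1, 1, 1, 1, 1, 1, 1),
    ## tissue-level amplitude relative to a1 (the bulb's response exceeds
    ## the cortical regions' several-fold once partial-volume dilution of a
    ## ~15-voxel structure under a 4 mm kernel is taken into account)
    amp  = c(3, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  rois
}

## Elliptical "brain" mask inscribed in the grid with a small margin.
make_brain_mask <- function(grid_shape) {
  cx <- (grid_shape + 1) / 2
  ax <- grid_shape * 0.45
  idx <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                     z = seq_len(grid_shape[3]))
  v <- ((idx$x - cx[1]) / ax[1])^2 + ((idx$y - cx[2]) / ax[2])^2 +
    ((idx$z - cx[3]) / ax[3])^2
  array(v <= 1, dim = grid_shape)
}

## Integer label volume (0 = background) built from a layout data frame.
roi_label_array <- function(layout, grid_shape) {
  lab <- array(0L, dim = grid_shape)
  idx <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                     z = seq_len(grid_shape[3]))
  for (i in seq_len(nrow(layout))) {
    r <- layout[i, ]
    inside <- if (r$shape == "sphere") {
      (idx$x - r$cx)^2 + (idx$y - r$cy)^2 + (idx$z - r$cz)^2 <= r$sx^2
    } else {
      abs(idx$x - r$cx) <= r$sx & abs(idx$y - r$cy) <= r$sy &
        abs(idx$z - r$cz) <= r$sz
    }
    if (!any(inside))
      stop(sprintf("region '%s' contains no voxels on this grid", r$name))
    lab[inside] <- i
  }
  structure(lab, names_table = stats::setNames(seq_len(nrow(layout)),
                                               layout$name))
}

## Static multiplicative attenuation field for one acquisition condition.
## The EPI-like field drops to 0.05 in a zone around the bulb-like region
## (susceptibility artifact from the nearby air cavities); the
## T2prep-like field is unity.
dropout_field <- function(cfg, condition = cfg$dropout) {
  if (is.array(condition)) return(condition)
  gs <- cfg$grid_shape
  if (condition %in% c("none", "t2prep")) return(array(1, dim = gs))
  bulb <- cfg$roi_layout[cfg$roi_layout$shape == "sphere", ][1, ]
  if (is.na(bulb$name)) bulb <- cfg$roi_layout[1, ]
  idx <- expand.grid(x = seq_len(gs[1]), y = seq_len(gs[2]),
                     z = seq_len(gs[3]))
  d <- sqrt((idx$x - bulb$cx)^2 + (idx$y - bulb$cy)^2 + (idx$z - bulb$cz)^2)
  ## plateau of strong attenuation out to 4 voxels, smooth recovery by 8
  s <- pmin(pmax((d - 4) / 4, 0), 1)
  w <- s * s * (3 - 2 * s)                   # smoothstep
  array(0.05 + 0.95 * w, dim = gs)
}

## Per-volume fractional response for one amplitude/habituation/shape set.
response_curve <- function(schedule, a, h, rho, t1, t2, w, tau) {
  if (tau <= 0) stop("post-stimulus transition time constant must be positive")
  s <- schedule
  sd_b <- w / (2 * sqrt(2 * log(2)))
  r <- numeric(s$n_volumes)
  n_b <- min(s$n_blocks, length(h))
  for (b in seq_len(n_b)) {
    b_start <- s$initial_off_seconds + (b - 1) * (s$on_seconds + s$off_seconds)
    tt <- s$times - b_start
    shape <- exp(-(tt - t1)^2 / (2 * sd_b^2)) +
      rho * exp(-(tt - t2)^2 / (2 * sd_b^2))
    in_b <- s$times >= b_start & s$times < b_start + s$on_seconds
    m <- mean(shape[in_b])                   # on-window mean = a * h[b]
    end_val <- (exp(-(s$on_seconds - t1)^2 / (2 * sd_b^2)) +
                  rho * exp(-(s$on_seconds - t2)^2 / (2 * sd_b^2))) / m
    after <- s$times >= b_start + s$on_seconds
    r[in_b] <- r[in_b] + a * h[b] * shape[in_b] / m
    r[after] <- r[after] +
      a * h[b] * end_val * exp(-(s$times[after] - b_start - s$on_seconds) / tau)
  }
  r
}

#' Per-volume fractional response template of the phantom
#'
#' The noiseless fractional signal change of a responding voxel over the
#' whole paradigm: within each on-block a bi-phasic pair of Gaussian peaks
#' scaled by the block's habituation multiplier, an exponential post-stimulus
#' transition after each block, and exactly zero before the first block.
#'
#' @param schedule a [build_paradigm()] schedule.
#' @param cfg a [sim_config()].
#' @param sign `"positive"` (amplitude `a1`, multipliers `h`, second-peak
#'   ratio `cfg$rho`) or `"negative"` (amplitude `-a_neg`, multipliers
#'   `h_neg`).
#' @return Numeric vector of length `schedule$n_volumes` (fractional units).
#' @export
response_template <- function(schedule, cfg, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (sign == "positive")
    response_curve(schedule, cfg$a1, cfg$h, cfg$rho,
                   cfg$t1_s, cfg$t2_s, cfg$w_s, cfg$tau_trans_s)
  else
    -response_curve(schedule, cfg$a_neg, cfg$h_neg, cfg$rho,
                    cfg$t1_s, cfg$t2_s, cfg$w_s, cfg$tau_trans_s)
}

#' Simulate a synthetic 4-D BOLD dataset with ground truth
#'
#' Generates one scan: voxel value =
#' `baseline * dropout(x) * (1 + response(t)) + drift(t) + respiration(t) +
#' thermal noise`. Responding voxels are placed according to
#' `cfg$roi_layout`; the ground truth records their masks, the noiseless
#' per-block relative signal change of every voxel (computed with the same
#' second-half-of-preceding-off baseline rule the analysis uses), and the
#' respiratory trace for nuisance regression.
#'
#' @param schedule a [build_paradigm()] schedule.
#' @param cfg a [sim_config()]; `cfg$grid_shape` must be able to contain
#'   every region of the layout.
#' @param seed integer; overrides `cfg$seed`. Identical seed and
#'   configuration give bit-identical output.
#' @param delay_s hemodynamic delay used when tabulating the ground-truth
#'   per-block signal change.
#' @return A list with elements `bold` (class `bold4d`: `data` 4-D array,
#'   `tr_seconds`, `voxel_mm`, `affine`, `brain_mask`) and `truth` (class
#'   `ground_truth`: `pos_mask`, `neg_mask`, `true_delta` — a 4-D array of
#'   per-block percent signal change, zero outside the responding masks —
#'   `roi_labels`, `nuisance_traces`, `dropout`).
#' @export
simulate_bold <- function(schedule, cfg, seed = cfg$seed, delay_s = 6) {
  stopifnot(inherits(schedule, "paradigm_schedule"),
            inherits(cfg, "sim_config"))
  gs <- cfg$grid_shape
  layout <- cfg$roi_layout
  if (any(layout$cx - layout$sx < 1 | layout$cx + layout$sx > gs[1] |
            layout$cy - layout$sy < 1 | layout$cy + layout$sy > gs[2] |
            layout$cz - layout$sz < 1 | layout$cz + layout$sz > gs[3]))
    stop("grid is too small to contain the requested regions")
  set.seed(seed)
  n <- schedule$n_volumes
  nvox <- prod(gs)
  labels <- roi_label_array(layout, gs)

  ## per-region response curves (regions sharing sign and rho share a curve)
  curves <- matrix(0, n, nrow(layout))
  for (i in seq_len(nrow(layout))) {
    r <- layout[i, ]
    amp <- if (is.null(r$amp)) 1 else r$amp
    curves[, i] <- if (r$sign > 0)
      response_curve(schedule, amp * cfg$a1, cfg$h, r$rho,
                     cfg$t1_s, cfg$t2_s, cfg$w_s, cfg$tau_trans_s)
    else
      -response_curve(schedule, amp * cfg$a_neg, cfg$h_neg, r$rho,
                      cfg$t1_s, cfg$t2_s, cfg$w_s, cfg$tau_trans_s)
  }

  att <- dropout_field(cfg)
  base_vol <- as.vector(cfg$baseline_intensity * att)

  phi_d <- stats::runif(1, 0, 2 * pi)
  phi_r <- stats::runif(1, 0, 2 * pi)
  drift <- cfg$drift_amp * sin(2 * pi * schedule$times / cfg$drift_period_s +
                                 phi_d)
  resp <- cfg$resp_amp * sin(2 * pi * cfg$resp_freq_hz * schedule$times +
                               phi_r)

  ## assemble time-by-voxel, then reshape
  m <- matrix(base_vol, n, nvox, byrow = TRUE)
  lab_vec <- as.vector(labels)
  for (i in seq_len(nrow(layout))) {
    vsel <- which(lab_vec == i)
    m[, vsel] <- m[, vsel] * (1 + curves[, i])
  }
  m <- m + drift + resp
  if (cfg$sigma_thermal > 0)
    m <- m + matrix(stats::rnorm(n * nvox, 0, cfg$sigma_thermal), n, nvox)

  bold <- new_bold4d(array(t(m), dim = c(gs, n)), schedule$tr_seconds,
                     cfg$voxel_mm, make_brain_mask(gs))

  ## noiseless per-block truth via the analysis baseline rule
  win <- paradigm_windows(schedule, delay_s)
  true_delta <- array(0, dim = c(gs, schedule$n_blocks))
  td <- matrix(0, nrow(layout), schedule$n_blocks)
  for (i in seq_len(nrow(layout))) {
    x <- cfg$baseline_intensity * (1 + curves[, i])
    td[i, ] <- vapply(seq_len(schedule$n_blocks), function(b) {
      B <- mean(x[win$base[[b]]])
      100 * (mean(x[win$on[[b]]]) - B) / B
    }, numeric(1))
  }
  for (b in seq_len(schedule$n_blocks)) {
    vol <- array(0, dim = gs)
    for (i in seq_len(nrow(layout))) vol[labels == i] <- td[i, b]
    true_delta[, , , b] <- vol
  }

  truth <- structure(list(
    pos_mask = labels > 0 & array(layout$sign[pmax(labels, 1)] > 0, dim = gs),
    neg_mask = labels > 0 & array(layout$sign[pmax(labels, 1)] < 0, dim = gs),
    true_delta = true_delta,
    roi_labels = labels,
    roi_names = layout$name,
    nuisance_traces = data.frame(respiratory = resp),
    dropout = att,
    delay_s = delay_s
  ), class = "ground_truth")
  list(bold = bold, truth = truth)
}

#' Simulate a scan/re-scan pair with shared truth
#'
#' Two datasets from the same configuration (identical response fields,
#' region placement and dropout) with independent noise realisations, for
#' test-retest reproducibility studies.
#'
#' @param schedule a [build_paradigm()] schedule.
#' @param cfg a [sim_config()].
#' @param seed_a,seed_b distinct seeds for the two noise realisations.
#' @param delay_s hemodynamic delay for the ground-truth tabulation.
#' @return List with elements `scan` and `rescan`, each as returned by
#'   [simulate_bold()].
#' @export
simulate_retest_pair <- function(schedule, cfg, seed_a, seed_b, delay_s = 6) {
  if (identical(seed_a, seed_b))
    stop("scan and re-scan seeds must differ")
  list(scan = simulate_bold(schedule, cfg, seed = seed_a, delay_s = delay_s),
       rescan = simulate_bold(schedule, cfg, seed = seed_b, delay_s = delay_s))
}

#' Simulate a per-subject table of block-wise signal changes
#'
#' Draws a subjects-by-blocks table of region-mean percent signal changes for
#' group-level habituation inference. Rows are exchangeable subjects with a
#' random intercept; the split between the subject and residual variance is
#' governed by `icc_between` (the correlation between any two blocks of the
#' same subject). The default block means and per-block between-subject
#' standard deviations describe a strongly habituating olfactory-bulb-scale
#' response measured on 14 subjects.
#'
#' The per-block spreads are pooled into one homoscedastic variance (their
#' mean) before decomposition: the table feeds a repeated-measures ANOVA
#' whose validity rests on equal within-subject variances, and carrying
#' block-dependent residual variances into a null simulation inflates its
#' false-rejection rate well above nominal.
#'
#' @param n_subjects number of simulated subjects.
#' @param mu per-block population means (percent).
#' @param sd_between per-block between-subject SDs (percent), pooled as
#'   described above.
#' @param icc_between within-subject inter-block correlation in `[0, 1)`.
#' @param seed integer seed.
#' @return Numeric matrix `n_subjects` x `length(mu)` (percent).
#' @export
simulate_subject_deltas <- function(n_subjects = 14,
                                    mu = c(2.2, 0.8, -0.2),
                                    sd_between = c(0.7, 0.5, 0.5) * sqrt(14),
                                    icc_between = 0.5, seed = 1L) {
  stopifnot(n_subjects >= 2, length(mu) == length(sd_between),
            icc_between >= 0, icc_between < 1)
  set.seed(seed)
  v_pooled <- mean(sd_between^2)
  sd_u <- sqrt(icc_between * v_pooled)
  sd_e <- sqrt((1 - icc_between) * v_pooled)
  u <- stats::rnorm(n_subjects, 0, sd_u)
  tab <- sapply(seq_along(mu), function(b)
    mu[b] + u + stats::rnorm(n_subjects, 0, sd_e))
  dimnames(tab) <- list(paste0("subj", seq_len(n_subjects)),
                        paste0("block", seq_along(mu)))
  tab
}
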