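#' One-way repeated-measures ANOVA across stimulation blocks
#'
#' Tests whether the region-mean relative signal change differs among the
#' stimulation blocks, with subjects as random blocks (within-subject
#' one-way design).
#'
#' @param delta_by_block numeric matrix, subjects in rows, blocks in
#'   columns; no missing cells.
#' @return List with `F`, `p`, and the degrees of freedom `df1`, `df2`.
#' @export
habituation_anova <- function(delta_by_block) {
  tab <- as.matrix(delta_by_block)
  if (anyNA(tab)) stop("repeated-measures ANOVA requires a complete table")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least two subjects and two blocks")
  df <- data.frame(
    y = as.vector(tab),
    subject = factor(rep(seq_len(nrow(tab)), ncol(tab))),
    block = factor(rep(seq_len(ncol(tab)), each = nrow(tab)))
  )
  fit <- stats::aov(y ~ block + Error(subject / block), data = df)
  s <- summary(fit)[["Error: subject:block"]][[1]]
  f <- s["block", "F value"]; p <- s["block", "Pr(>F)"]
  ## identical values across blocks: block and residual sums of squares are
  ## both numerically zero and the F ratio is noise over noise
  eps <- 1e-12 * (sum((tab - mean(tab))^2) + 1)
  if (!is.finite(f) ||
        (s["block", "Sum Sq"] < eps && s["Residuals", "Sum Sq"] < eps)) {
    f <- 0; p <- 1
  }
  list(F = f, p = p,
       df1 = s["block", "Df"], df2 = s["Residuals", "Df"])
}

#' Relative difference of later blocks versus block 1
#'
#' Per-subject relative difference `100 * (dS/S block k - dS/S block 1) /
#' group mean of dS/S block 1`, summarised as mean and standard error. The
#' group-mean denominator keeps subjects with small block-1 responses from
#' dominating.
#'
#' @param delta_block_k,delta_block_1 per-subject percent signal changes.
#' @return List with `mean`, `se` and the per-subject `values` (percent).
#' @export
relative_difference <- function(delta_block_k, delta_block_1) {
  stopifnot(length(delta_block_k) == length(delta_block_1))
  g <- mean(delta_block_1)
  if (g == 0) stop("group mean of block-1 dS/S is zero")
  v <- 100 * (delta_block_k - delta_block_1) / g
  list(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), values = v)
}

#' Paired comparison of two conditions across regions
#'
#' Per region: paired t-test between conditions, Benjamini-Hochberg
#' adjustment across regions, Cohen's d with the pooled standard deviation
#' `sqrt((sd_a^2 + sd_b^2) / 2)`, and the relative difference
#' `100 * (mean_a - mean_b) / mean_b`.
#'
#' @param values_a,values_b numeric matrices, subjects in rows and regions
#'   in columns (or vectors for a single region); pairing is by row.
#' @param roi_names optional region names.
#' @return Data frame per region: `roi`, `n`, `mean_a`, `mean_b`,
#'   `p_paired`, `q`, `rel_diff_pct`, `cohens_d`, `pooled_sd`.
#' @export
paired_compare <- function(values_a, values_b, roi_names = NULL) {
  a <- as.matrix(values_a); b <- as.matrix(values_b)
  stopifnot(all(dim(a) == dim(b)))
  if (nrow(a) < 2) stop("paired comparison needs at least two subjects")
  k <- ncol(a)
  if (is.null(roi_names)) roi_names <- colnames(a)
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(k))
  out <- data.frame(roi = roi_names, n = nrow(a),
                    mean_a = colMeans(a), mean_b = colMeans(b),
                    p_paired = NA_real_, q = NA_real_,
                    rel_diff_pct = NA_real_, cohens_d = NA_real_,
                    pooled_sd = NA_real_, row.names = NULL)
  for (i in seq_len(k)) {
    if (anyNA(a[, i]) || anyNA(b[, i])) next   # flagged missing, not zero
    d <- a[, i] - b[, i]
    out$p_paired[i] <- if (stats::sd(d) == 0) {
      if (mean(d) == 0) 1 else 0      # constant nonzero difference
    } else stats::t.test(a[, i], b[, i], paired = TRUE)$p.value
    out$pooled_sd[i] <- sqrt((stats::var(a[, i]) + stats::var(b[, i])) / 2)
    out$cohens_d[i] <- if (out$pooled_sd[i] == 0) 0 else
      (out$mean_a[i] - out$mean_b[i]) / out$pooled_sd[i]
    if (out$mean_b[i] != 0)
      out$rel_diff_pct[i] <- 100 * (out$mean_a[i] - out$mean_b[i]) /
        out$mean_b[i]
  }
  out$q <- stats::p.adjust(out$p_paired, method = "BH")
  out
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`: 0 for disjoint non-empty masks, 1 for
#' identical non-empty masks. Two empty masks are defined as perfect
#' agreement of absence (Dice 1, with a note).
#'
#' @param mask_a,mask_b logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' dice(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))  # 2*1/(2+1)
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(as.array(mask_a)) == dim(as.array(mask_b))))
    stop("masks must have identical shape")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) {
    message("both masks empty: Dice defined as 1 (agreement of absence)")
    return(1)
  }
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Intraclass correlation of paired measurements
#'
#' Single-measure intraclass correlation from the two-way mean-squares
#' decomposition with measurements (scan/re-scan) as random raters:
#' ICC(2,1), absolute agreement, by default; ICC(3,1), consistency, by flag.
#'
#' @param scan_values,rescan_values paired numeric vectors (length >= 2).
#' @param type `"ICC2_1"` (absolute agreement) or `"ICC3_1"` (consistency).
#' @return ICC in `[-1, 1]`, or `NA` when the data have no variance.
#' @export
icc <- function(scan_values, rescan_values, type = c("ICC2_1", "ICC3_1")) {
  type <- match.arg(type)
  x <- as.numeric(scan_values); y <- as.numeric(rescan_values)
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("ICC needs at least two paired values")
  n <- length(x); k <- 2
  tab <- cbind(x, y)
  if (stats::var(as.vector(tab)) == 0) return(NA_real_)
  grand <- mean(tab)
  row_m <- rowMeans(tab); col_m <- colMeans(tab)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((tab - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "ICC3_1")
    (msr - mse) / (msr + (k - 1) * mse)
  else
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Count visible voxels of a region on one image slice
#'
#' Applies the slice-level visibility rule: the threshold is two standard
#' deviations below the mean intensity of the whole slice, and in-mask
#' voxels above it are counted (a measure of how much of a small structure
#' survives susceptibility dropout).
#'
#' @param image_slice numeric 2-D array (one slice).
#' @param roi_mask logical 2-D array, same shape, non-empty.
#' @return Integer count.
#' @export
roi_visibility_count <- function(image_slice, roi_mask) {
  stopifnot(all(dim(image_slice) == dim(roi_mask)))
  if (!any(roi_mask)) stop("region mask is empty on this slice")
  thr <- mean(image_slice) - 2 * stats::sd(image_slice)
  sum(image_slice[roi_mask] >= thr)   # >= so a uniform slice is fully visible
}

#' Region-level summary of activation and response maps
#'
#' Means over the sign-classified activated voxels of each region: voxel
#' counts, per-block and overall percent signal change, tSNR and CNR.
#' Regions with no activated voxel of the requested sign are flagged
#' missing (NA), not zero. Voxels with non-finite tSNR (constant series)
#' are excluded from the tSNR/CNR means.
#'
#' @param resp a [block_response()].
#' @param amap an `activation_map` on the same grid.
#' @param roi_labels integer 3-D label array.
#' @param sign `"positive"` or `"negative"`.
#' @param roi_names optional names for labels `1..K`.
#' @return Data frame, one row per region.
#' @export
roi_summarize <- function(resp, amap, roi_labels, sign = "positive",
                          roi_names = NULL) {
  stopifnot(sign %in% c("positive", "negative"),
            all(dim(roi_labels) == dim(resp$tsnr)))
  k <- max(roi_labels)
  if (k < 1) stop("label image contains no regions")
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(k))
  want <- if (sign == "positive") 1 else 2
  nb <- dim(resp$delta_pct)[4]
  out <- data.frame(roi = roi_names, n_active = 0L,
                    matrix(NA_real_, k, nb,
                           dimnames = list(NULL, paste0("delta_block",
                                                        seq_len(nb)))),
                    delta_overall = NA_real_, tsnr = NA_real_,
                    cnr = NA_real_)
  for (i in seq_len(k)) {
    sel <- roi_labels == i & amap$sign == want
    out$n_active[i] <- sum(sel)
    if (!any(sel)) next
    for (b in seq_len(nb))
      out[i, paste0("delta_block", b)] <- mean(resp$delta_pct[, , , b][sel])
    out$delta_overall[i] <- mean(resp$delta_overall_pct[sel])
    fin <- sel & is.finite(resp$tsnr)
    if (any(fin)) {
      out$tsnr[i] <- mean(resp$tsnr[fin])
      out$cnr[i] <- mean(resp$cnr[fin])
    }
  }
  out
}
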