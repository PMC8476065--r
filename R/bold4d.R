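#' Construct a 4-D BOLD container
#'
#' Light container for a 4-D BOLD series: the data array (x, y, z, t), the
#' repetition time, voxel geometry (RAS+ affine derived from the isotropic
#' voxel size unless supplied) and a brain mask.
#'
#' @param data 4-D numeric array (x, y, z, t).
#' @param tr_seconds repetition time (s).
#' @param voxel_mm isotropic voxel size (mm) or length-3 vector.
#' @param brain_mask logical 3-D array; defaults to all-TRUE.
#' @param affine optional 4 x 4 spatial transform.
#' @return Object of class `bold4d`.
#' @export
new_bold4d <- function(data, tr_seconds, voxel_mm = 1.5, brain_mask = NULL,
                       affine = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4, tr_seconds > 0)
  vox <- rep(voxel_mm, length.out = 3)
  if (is.null(affine)) {
    affine <- diag(c(vox, 1))
    affine[1:3, 4] <- -vox * (dim(data)[1:3] - 1) / 2
  }
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = dim(data)[1:3])
  stopifnot(all(dim(brain_mask) == dim(data)[1:3]))
  structure(list(data = data, tr_seconds = tr_seconds, voxel_mm = vox,
                 affine = affine, brain_mask = brain_mask,
                 preproc_log = list()),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD 4-D series: %d x %d x %d voxels x %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  TR %g s, voxel %s mm, %d voxels in brain mask\n",
              x$tr_seconds, paste(x$voxel_mm, collapse = " x "),
              sum(x$brain_mask)))
  if (length(x$preproc_log))
    cat("  preprocessing:",
        paste(vapply(x$preproc_log, `[[`, "", "stage"), collapse = " -> "),
        "\n")
  invisible(x)
}

## time-by-voxel matrix of the in-mask voxels (and the inverse)
ts_matrix <- function(bold, voxels = which(bold$brain_mask)) {
  d <- dim(bold$data)
  m <- matrix(bold$data, prod(d[1:3]), d[4])[voxels, , drop = FALSE]
  t(m)
}

set_ts_matrix <- function(bold, m, voxels = which(bold$brain_mask)) {
  d <- dim(bold$data)
  flat <- matrix(bold$data, prod(d[1:3]), d[4])
  flat[voxels, ] <- t(m)
  bold$data <- array(flat, dim = d)
  bold
}

## 3-D map (NA outside the given voxels) from a per-voxel vector
map_from_values <- function(values, voxels, grid_shape, fill = NA_real_) {
  v <- array(fill, dim = grid_shape)
  v[voxels] <- values
  v
}

log_stage <- function(bold, stage, ...) {
  bold$preproc_log <- c(bold$preproc_log, list(list(stage = stage, ...)))
  bold
}
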