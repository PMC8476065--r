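#' Write a 4-D BOLD series as NIfTI-1
#'
#' @param bold a `bold4d`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path) {
  stopifnot(inherits(bold, "bold4d"))
  img <- RNifti::asNifti(bold$data)
  img <- RNifti::`pixdim<-`(img, c(bold$voxel_mm, bold$tr_seconds))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D BOLD series from NIfTI-1
#'
#' The repetition time is taken from the header's fourth pixdim unless
#' overridden; a missing or zero header TR without an override is an error.
#'
#' @param path NIfTI file.
#' @param tr_seconds optional TR override (s).
#' @param brain_mask optional logical 3-D array or path to a mask NIfTI.
#' @return A `bold4d`.
#' @export
read_bold_nifti <- function(path, tr_seconds = NULL, brain_mask = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("not a readable NIfTI-1 file: ", path, " (",
                         conditionMessage(e), ")"))
  if (length(dim(img)) != 4)
    stop("expected a 4-D BOLD image, got ", length(dim(img)), " dimensions")
  pd <- RNifti::pixdim(img)
  tr <- if (!is.null(tr_seconds)) tr_seconds else pd[4]
  if (is.null(tr) || !is.finite(tr) || tr <= 0)
    stop("repetition time missing from header; pass tr_seconds explicitly")
  if (is.character(brain_mask))
    brain_mask <- array(as.logical(RNifti::readNifti(brain_mask) > 0),
                        dim = dim(img)[1:3])
  if (!is.null(brain_mask) && !all(dim(brain_mask) == dim(img)[1:3]))
    stop("brain mask dimensions do not match the image")
  new_bold4d(array(as.numeric(img), dim = dim(img)), tr, pd[1:3],
             brain_mask, affine = structure(RNifti::xform(img),
                                            class = NULL))
}

#' Write a 3-D map (statistic, label or mask volume) as NIfTI-1
#'
#' @param map 3-D numeric/integer/logical array.
#' @param path output file.
#' @param voxel_mm voxel size (mm).
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_mm = 1.5) {
  m <- map
  m[is.na(m)] <- 0
  img <- RNifti::asNifti(array(as.numeric(m), dim = dim(map)))
  img <- RNifti::`pixdim<-`(img, rep(voxel_mm, length.out = 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a paradigm schedule as tab-separated text
#'
#' One row per volume (`volume_index`, `time_s`, `label`, `block_index`)
#' preceded by comment lines holding the paradigm parameters, so the
#' schedule round-trips losslessly through [read_schedule()].
#'
#' @param schedule a `paradigm_schedule`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "paradigm_schedule"))
  hdr <- sprintf(
    "# %s=%g",
    c("tr_seconds", "initial_off_seconds", "n_blocks", "on_seconds",
      "off_seconds", "pulse_on_seconds", "pulse_off_seconds"),
    c(schedule$tr_seconds, schedule$initial_off_seconds, schedule$n_blocks,
      schedule$on_seconds, schedule$off_seconds, schedule$pulse_on_seconds,
      schedule$pulse_off_seconds))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(volume_index = seq_len(schedule$n_volumes) - 1L,
               time_s = schedule$times, label = schedule$labels,
               block_index = schedule$block_index),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a paradigm schedule written by [write_schedule()]
#'
#' @param path schedule TSV.
#' @return A `paradigm_schedule`.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "="))
  if (is.null(kv) || nrow(kv) < 7)
    stop("malformed schedule file: missing parameter header lines")
  par <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  g <- function(k) unname(par[k])
  sched <- build_paradigm(g("tr_seconds"), g("initial_off_seconds"),
                          g("n_blocks"), g("on_seconds"), g("off_seconds"),
                          g("pulse_on_seconds"), g("pulse_off_seconds"))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("volume_index", "label", "block_index")
  if (!all(need %in% names(tab)))
    stop("malformed schedule file: columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), " missing")
  if (nrow(tab) != sched$n_volumes ||
        !all(tab$label == sched$labels) ||
        !all(tab$block_index == sched$block_index))
    stop("schedule rows are inconsistent with the header parameters")
  sched
}

#' Write per-volume nuisance traces as tab-separated columns
#'
#' @param traces data frame or matrix, one row per volume.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  utils::write.table(as.data.frame(traces), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-volume nuisance traces
#'
#' @param path traces TSV.
#' @return Data frame, one row per volume.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Write and read a pipeline run configuration (YAML)
#'
#' The configuration round-trips losslessly: `read_run_config(
#' write_run_config(cfg, path))` restores every field.
#'
#' @param config named list of run settings (see [run_pipeline()]).
#' @param path YAML file.
#' @return `path` invisibly (write) / the configuration list (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  yaml::read_yaml(path)
}
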