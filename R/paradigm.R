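#' Build a block-design odor-stimulation paradigm schedule
#'
#' Constructs the volume-by-volume schedule of a pulsed block paradigm: an
#' initial stimulus-off period followed by `n_blocks` cycles of a stimulus-on
#' period (during which the odorant is delivered as a train of short pulses)
#' and a stimulus-off period. The default arguments reproduce a 10-minute
#' paradigm of 60 s off followed by three cycles of 60 s pulsed-on
#' (20 repetitions of 1 s odor + 2 s odorless carrier) and 120 s off,
#' sampled at TR = 2 s.
#'
#' Volume `v` (1-based) is taken to be acquired at time `(v - 1) * tr_seconds`
#' from paradigm onset, and is labelled `"ON"` when that time falls inside a
#' stimulus-on interval. `block_index` is 0 before the first block and `b`
#' from the onset of block `b` until the onset of block `b + 1` (the on
#' period plus its trailing off period).
#'
#' @param tr_seconds repetition time in seconds (sampling interval).
#' @param initial_off_seconds duration of the leading stimulus-off period (s).
#' @param n_blocks number of stimulation blocks.
#' @param on_seconds,off_seconds durations of each stimulus-on period and of
#'   the stimulus-off period that follows it (s).
#' @param pulse_on_seconds,pulse_off_seconds durations of a single odor pulse
#'   and of the odorless gap after it (s); pulses are repeated back-to-back
#'   for as long as they fit inside the on period.
#' @return An object of class `paradigm_schedule`: a list with fields
#'   `tr_seconds`, `n_volumes`, `times` (acquisition times, s),
#'   `initial_off_seconds`, `n_blocks`, `on_seconds`, `off_seconds`,
#'   `pulse_on_seconds`, `pulse_off_seconds`, `labels` (`"ON"`/`"OFF"` per
#'   volume), `block_index` (integer per volume), and `pulse_train`
#'   (data frame of pulse `onset_s` and `duration_s`).
#' @examples
#' sched <- build_paradigm()
#' sched$n_volumes                    # 300 volumes = 600 s at TR 2 s
#' table(sched$labels)
#' @export
build_paradigm <- function(tr_seconds = 2, initial_off_seconds = 60,
                           n_blocks = 3, on_seconds = 60, off_seconds = 120,
                           pulse_on_seconds = 1, pulse_off_seconds = 2) {
  stopifnot(tr_seconds > 0, on_seconds > 0, off_seconds > 0,
            pulse_on_seconds > 0, pulse_off_seconds > 0,
            initial_off_seconds >= 0)
  if (n_blocks < 1)
    stop("paradigm must contain at least one stimulation block")
  total <- initial_off_seconds + n_blocks * (on_seconds + off_seconds)
  n_vol <- round(total / tr_seconds)
  if (abs(n_vol * tr_seconds - total) >= tr_seconds / 2 - 1e-9)
    stop(sprintf(paste0("total paradigm duration (%g s) is not divisible by ",
                        "the repetition time (%g s)"), total, tr_seconds))
  times <- (seq_len(n_vol) - 1) * tr_seconds

  labels <- rep("OFF", n_vol)
  block_index <- integer(n_vol)
  pulses_per_block <- floor(on_seconds / (pulse_on_seconds + pulse_off_seconds))
  onsets <- numeric(0)
  for (b in seq_len(n_blocks)) {
    b_start <- initial_off_seconds + (b - 1) * (on_seconds + off_seconds)
    labels[times >= b_start & times < b_start + on_seconds] <- "ON"
    block_index[times >= b_start] <- b
    onsets <- c(onsets, b_start +
                  (seq_len(pulses_per_block) - 1) *
                    (pulse_on_seconds + pulse_off_seconds))
  }
  structure(list(
    tr_seconds = tr_seconds, n_volumes = n_vol, times = times,
    initial_off_seconds = initial_off_seconds, n_blocks = n_blocks,
    on_seconds = on_seconds, off_seconds = off_seconds,
    pulse_on_seconds = pulse_on_seconds, pulse_off_seconds = pulse_off_seconds,
    labels = labels, block_index = block_index,
    pulse_train = data.frame(onset_s = onsets,
                             duration_s = rep(pulse_on_seconds, length(onsets)))
  ), class = "paradigm_schedule")
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  cat(sprintf(
    "Paradigm schedule: %d volumes, TR %g s (%g s total)\n",
    x$n_volumes, x$tr_seconds, x$n_volumes * x$tr_seconds))
  cat(sprintf("  %g s off + %d x (%g s on / %g s off); %d odor pulses/block\n",
              x$initial_off_seconds, x$n_blocks, x$on_seconds, x$off_seconds,
              nrow(x$pulse_train) / x$n_blocks))
  cat(sprintf("  %d ON / %d OFF volumes\n",
              sum(x$labels == "ON"), sum(x$labels == "OFF")))
  invisible(x)
}

## Sampling windows for per-block quantification. The hemodynamic delay shifts
## every window forward by round(delay / tr) volumes (clipped at the series
## end). Baseline windows follow the second-half-of-the-preceding-off rule:
## for block 1 the second half of the initial off period, for block b > 1 the
## second half of the off period trailing block b - 1.
paradigm_windows <- function(schedule, delay_s = 6) {
  stopifnot(inherits(schedule, "paradigm_schedule"), delay_s >= 0)
  s <- schedule
  shift <- round(delay_s / s$tr_seconds)
  n <- s$n_volumes
  clip <- function(idx) {
    idx <- idx + shift
    idx[idx >= 1 & idx <= n]
  }
  on <- base <- vector("list", s$n_blocks)
  for (b in seq_len(s$n_blocks)) {
    b_start <- s$initial_off_seconds + (b - 1) * (s$on_seconds + s$off_seconds)
    on[[b]] <- clip(which(s$times >= b_start & s$times < b_start + s$on_seconds))
    if (b == 1) {
      lo <- s$initial_off_seconds / 2
      hi <- s$initial_off_seconds
    } else {
      hi <- b_start
      lo <- b_start - s$off_seconds / 2
    }
    base[[b]] <- clip(which(s$times >= lo & s$times < hi))
  }
  list(on = on, base = base, shift_volumes = shift)
}

## ON/OFF sample index sets for the activation test, with the same
## hemodynamic shift applied to the labels.
paradigm_on_off <- function(schedule, delay_s = 6) {
  shift <- round(delay_s / schedule$tr_seconds)
  lab <- c(rep("OFF", shift), schedule$labels)[seq_len(schedule$n_volumes)]
  list(on = which(lab == "ON"), off = which(lab == "OFF"), labels = lab)
}
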