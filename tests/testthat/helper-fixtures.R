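## Shared fixtures and independent oracles. Heavy simulated objects are
## memoized so several test files can reuse them within one session.

paper_schedule <- function() build_paradigm()

## Small phantom configuration for fast unit tests: 14 x 14 x 10 grid with
## one bulb-like sphere, one positive cuboid and one negative cuboid.
tiny_layout <- function() {
  data.frame(
    name = c("bulb", "cortex", "negative"),
    shape = c("sphere", "cuboid", "cuboid"),
    cx = c(7, 9, 4), cy = c(4, 9, 9), cz = c(4, 5, 6),
    sx = c(1.2, 2, 1), sy = c(1.2, 2, 1), sz = c(1.2, 1, 1),
    sign = c(1, 1, -1), rho = c(0.2, 1, 1), amp = c(3, 1, 1),
    stringsAsFactors = FALSE
  )
}

tiny_cfg <- function(...) {
  args <- list(...)
  if (!"roi_layout" %in% names(args)) args$roi_layout <- tiny_layout()
  do.call(sim_config, c(list(grid_shape = c(14L, 14L, 10L)), args))
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## default-condition phantom analysed through the detection and
## quantification paths (the workhorse fixture for activation tests)
shared_default_run <- function() {
  memo("default_run", {
    sched <- paper_schedule()
    sim <- simulate_bold(sched, sim_config(), seed = 7)
    det <- preprocess_bold(sim$bold, lp_cutoff_hz = 0,
                           traces = sim$truth$nuisance_traces)
    quant <- preprocess_bold(sim$bold, traces = sim$truth$nuisance_traces,
                             protect = protect_regressors(sched))
    list(sched = sched, sim = sim, det = det, quant = quant,
         amap = ks_activation_map(det, sched),
         resp = block_response(quant, sched))
  })
}

## ---- independent oracles ----

## per-second timeline enumeration of a block paradigm (paradigm oracle)
enumerate_paradigm <- function(initial_off, n_blocks, on_s, off_s,
                               pulse_on, pulse_off) {
  total <- initial_off + n_blocks * (on_s + off_s)
  step <- 0.5                                # half-second resolution
  tt <- seq(0, total - step, by = step)
  on <- rep(FALSE, length(tt))
  pulses <- 0
  for (b in seq_len(n_blocks)) {
    b0 <- initial_off + (b - 1) * (on_s + off_s)
    on[tt >= b0 & tt < b0 + on_s] <- TRUE
    t_p <- b0
    while (t_p + pulse_on + pulse_off <= b0 + on_s + 1e-9) {
      pulses <- pulses + 1
      t_p <- t_p + pulse_on + pulse_off
    }
  }
  list(total_s = total, on_seconds_total = sum(on) * step, n_pulses = pulses)
}

## brute-force two-sample KS statistic: scan every pooled point with plain
## proportions (no sorting/cumsum shortcuts)
brute_ks_D <- function(x, y) {
  max(vapply(c(x, y), function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

## full-enumeration permutation p-value using the brute-force statistic
brute_ks_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  d_obs <- brute_ks_D(x, y)
  combs <- utils::combn(length(pooled), n1)
  mean(apply(combs, 2, function(idx)
    brute_ks_D(pooled[idx], pooled[-idx])) >= d_obs - 1e-12)
}

## textbook two-way ANOVA mean squares for a subjects x measurements table
anova_ms_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  ssr <- k * sum((rowMeans(tab) - grand)^2)
  ssc <- n * sum((colMeans(tab) - grand)^2)
  sst <- sum((tab - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

## ICC(2,1) from the oracle mean squares
icc21_oracle <- function(x, y) {
  ms <- anova_ms_oracle(cbind(x, y))
  n <- length(x); k <- 2
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
}
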