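# Independent oracles used across tests.

# Naive minute-loop simulator: applies the analytic one-step solution of the
# well-mixed box model directly, independently of the package's vectorised
# implementation.
naive_trace <- function(g_per_minute, alpha, volume, c0 = 0) {
  n <- length(g_per_minute)
  out <- numeric(n)
  c_prev <- c0
  for (t in seq_len(n)) {
    k <- exp(-alpha)
    out[t] <- g_per_minute[t] / (alpha * volume) * (1 - k) + c_prev * k
    c_prev <- out[t]
  }
  out
}

# mass-balance oracle for the daily mean under full within-day decay:
# mean = G * minutes_on / (alpha * V * horizon)
oracle_mean <- function(g, minutes_on, ach = 15, volume = 30, horizon = 1440) {
  g * minutes_on / ((ach / 60) * volume * horizon)
}

# per-minute emission vector from a schedule tibble
schedule_rates <- function(sched, horizon = 1440) {
  g <- numeric(horizon)
  for (i in seq_len(nrow(sched))) {
    idx <- (sched$start[i] + 1):(sched$start[i] + sched$duration[i])
    g[idx] <- g[idx] + sched$rate[i]
  }
  g
}

ref_kitchen <- function() kitchen(30, 15)

# demo IER fit shared across tests (anchors: RR 3 at exclusive-TSF child
# exposure, RR 2 at 75% exposure reduction)
demo_ier <- function() calibrate_ier()
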