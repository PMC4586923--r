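# Independent oracles used across tests; deliberately re-derived here rather
# than calling package internals.

# Hodgkin-Huxley steady-state membrane current from the canonical rate
# functions (independent implementation for cross-checks).
hh_oracle_current <- function(v, gna = 120, gk = 36, gl = 0.3,
                              ena = 50, ek = -77, el = -54.4) {
  am <- 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
  bm <- 4 * exp(-(v + 65) / 18)
  ah <- 0.07 * exp(-(v + 65) / 20)
  bh <- 1 / (1 + exp(-(v + 35) / 10))
  an <- 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))
  bn <- 0.125 * exp(-(v + 65) / 80)
  m <- am / (am + bm); h <- ah / (ah + bh); n <- an / (an + bn)
  gna * m^3 * h * (v - ena) + gk * n^4 * (v - ek) + gl * (v - el)
}

# Boltzmann and its exact derivative (for closed-form DIC checks).
boltz <- function(v, half, slope) 1 / (1 + exp(-(v - half) / slope))
dboltz <- function(v, half, slope) {
  b <- boltz(v, half, slope)
  b * (1 - b) / slope
}

# A synthetic voltage trace with triangular spikes at given times (ms).
synthetic_spike_trace <- function(spike_times, duration, dt = 0.5,
                                  base = -60, peak = 20) {
  tt <- seq(0, duration, by = dt)
  vv <- rep(base, length(tt))
  for (ts in spike_times) {
    vv[tt >= ts - 1 & tt < ts] <- peak   # instantaneous up, 1 ms wide
    vv[tt >= ts & tt < ts + 1] <- peak
  }
  data.frame(time = tt, v = vv)
}
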