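## Precompile a model into an index-based evaluator for the ODE solver:
## gates and pool are resolved to integer slots once, so the right-hand
## side does no name lookups.
compile_model <- function(model) {
  snames <- state_names(model)
  idx <- function(nm) match(nm, snames)
  gates <- list()
  currents <- list()
  for (cur in model$currents) {
    mi <- if (is.null(cur$activation)) NA_integer_
          else idx(paste0(cur$name, ".m"))
    hi <- if (is.null(cur$inactivation)) NA_integer_
          else idx(paste0(cur$name, ".h"))
    currents[[length(currents) + 1L]] <- list(
      gbar = cur$gbar, erev = cur$erev,
      mi = mi, p = if (is.na(mi)) 0L else cur$activation$exponent,
      hi = hi, q = if (is.na(hi)) 0L else cur$inactivation$exponent,
      ca_carry = cur$calcium_carrying)
    if (!is.na(mi))
      gates[[length(gates) + 1L]] <- list(i = mi, g = cur$activation)
    if (!is.na(hi))
      gates[[length(gates) + 1L]] <- list(i = hi, g = cur$inactivation)
  }
  ca_i <- if (is.null(model$calcium)) NA_integer_ else idx("Ca")
  list(snames = snames, gates = gates, currents = currents, ca_i = ca_i,
       pool = model$calcium, leak = model$leak, cap = model$capacitance,
       n = length(snames))
}

## Ionic + leak current for a compiled model at potential v, state y.
compiled_current <- function(cm, v, y) {
  tot <- cm$leak$g * (v - cm$leak$erev)
  for (cur in cm$currents) {
    x <- cur$gbar * (v - cur$erev)
    if (!is.na(cur$mi)) x <- x * y[cur$mi]^cur$p
    if (!is.na(cur$hi)) x <- x * y[cur$hi]^cur$q
    tot <- tot + x
  }
  tot
}

## State derivatives (gates + calcium) for a compiled model; v is the
## (possibly clamped) potential, y the state vector in compile order.
compiled_derivs <- function(cm, v, y) {
  d <- numeric(cm$n)
  ca <- if (!is.na(cm$ca_i)) y[cm$ca_i] else NULL
  for (gt in cm$gates) {
    xinf <- if (gt$g$ca_dependent) gt$g$inf(v, ca) else gt$g$inf(v)
    d[gt$i] <- (xinf - y[gt$i]) / gt$g$tau(v)
  }
  if (!is.na(cm$ca_i)) {
    i_ca <- 0
    for (cur in cm$currents) {
      if (!cur$ca_carry) next
      x <- cur$gbar * (v - cur$erev)
      if (!is.na(cur$mi)) x <- x * y[cur$mi]^cur$p
      if (!is.na(cur$hi)) x <- x * y[cur$hi]^cur$q
      i_ca <- i_ca + x
    }
    d[cm$ca_i] <- (-cm$pool$f * i_ca - y[cm$ca_i] + cm$pool$ca0) /
      cm$pool$tau
  }
  d
}

#' Time-domain simulation of a neuron model
#'
#' Integrates the full membrane equation with an adaptive stiff solver
#' (`deSolve::ode`, lsoda, relative tolerance 1e-8 by default).
#'
#' @param model A [neuron_model()].
#' @param duration Simulated time in ms (> 0).
#' @param i_app Applied current: scalar, or `function(t)` in ms; defaults to
#'   the model's `i_app`.
#' @param dt_out Output sampling step in ms.
#' @param v0 Initial potential (defaults to the lower end of the working
#'   range); the gating state is initialized at `steady_state(model, v0)`
#'   unless `init` is given.
#' @param init Optional full named initial state (gates + Ca).
#' @param rtol,atol Integrator tolerances.
#' @return A `dic_trace` data frame with columns `time`, `v`, one column per
#'   state variable, and `i_total` (total transmembrane current, uA/cm^2).
#' @export
simulate_model <- function(model, duration, i_app = NULL, dt_out = 0.1,
                           v0 = NULL, init = NULL, rtol = 1e-8, atol = 1e-8) {
  stopifnot(duration > 0)
  if (is.null(v0)) v0 <- model$v_range[1]
  if (is.null(init)) init <- steady_state(model, v0)
  iapp_fn <- if (is.null(i_app)) {
    ia <- model$i_app
    function(t) ia
  } else if (is.function(i_app)) i_app else {
    ia <- i_app
    function(t) ia
  }
  cm <- compile_model(model)
  y0 <- c(v0, unname(init[cm$snames]))
  rhs <- function(t, y, p) {
    v <- y[1]
    st <- y[-1]
    dv <- (-compiled_current(cm, v, st) + iapp_fn(t)) / cm$cap
    list(c(dv, compiled_derivs(cm, v, st)))
  }
  times <- seq(0, duration, by = dt_out)
  out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 20000)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf(
      "integrator failed near t = %.3f ms (stiff segment); last V = %.2f mV",
      max(out[, 1]), out[nrow(out), 2]))
  df <- as.data.frame(out)
  names(df) <- c("time", "v", cm$snames)
  df$i_total <- trace_total_current(model, df$v, df)
  class(df) <- c("dic_trace", "data.frame")
  df
}

## Integrate only the gating/calcium subsystem with V algebraically clamped.
## Returns time, i_total (at the clamped potential) and the state columns.
simulate_clamped <- function(model, v_clamp, times, init,
                             rtol = 1e-10, atol = 1e-10) {
  cm <- compile_model(model)
  if (cm$n == 0) {
    df <- data.frame(time = times,
                     i_total = compiled_current(cm, v_clamp, numeric(0)))
    class(df) <- c("dic_trace", "data.frame")
    return(df)
  }
  rhs <- function(t, y, p) list(compiled_derivs(cm, v_clamp, y))
  out <- deSolve::ode(unname(init[cm$snames]), times, rhs, NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 20000)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("clamped integration failed near t = %.3f ms at V = %g mV",
                 max(out[, 1]), v_clamp))
  df <- as.data.frame(out)
  names(df) <- c("time", cm$snames)
  itot <- trace_total_current(model, v_clamp, df)
  cbind(data.frame(time = df$time, i_total = itot), df[cm$snames])
}

## Vectorized total transmembrane current along a trace.
trace_total_current <- function(model, v, statedf) {
  tot <- model$leak$g * (v - model$leak$erev)
  for (cur in model$currents) {
    m <- if (is.null(cur$activation)) 1
         else statedf[[paste0(cur$name, ".m")]]^cur$activation$exponent
    h <- if (is.null(cur$inactivation)) 1
         else statedf[[paste0(cur$name, ".h")]]^cur$inactivation$exponent
    tot <- tot + cur$gbar * m * h * (v - cur$erev)
  }
  tot
}

## Kept for the clamp module's equilibration check: named-state derivatives.
model_derivs <- function(model, v, state) {
  cm <- compile_model(model)
  d <- compiled_derivs(cm, v, unname(state[cm$snames]))
  names(d) <- cm$snames
  d
}

#' Spike and burst statistics of a voltage trace
#'
#' Spikes are upward crossings of `spike_threshold` separated by at least
#' `refractory` ms. Bursts are groups of spikes separated by inter-spike
#' intervals larger than `burst_gap` (default: 5 times the median ISI).
#'
#' @param trace A `dic_trace` (from [simulate_model()]) or any data frame
#'   with `time` and `v` columns.
#' @param spike_threshold Crossing level in mV.
#' @param refractory Minimal spike separation in ms.
#' @param burst_gap ISI above which a new burst starts, in ms; `NULL` for the
#'   5 x median-ISI default.
#' @param discard Initial transient to drop, in ms.
#' @return List with `spike_times`, `isis`, `n_bursts`, `burst_isis` (list of
#'   per-burst ISI sequences), `spikes_per_burst`, `burst_period` (median
#'   interval between burst onsets, NA for < 2 bursts) and `duty_cycle`.
#'   A trace without spikes yields an empty (not an error) result.
#' @export
trace_statistics <- function(trace, spike_threshold = 0, refractory = 2,
                             burst_gap = NULL, discard = 0) {
  stopifnot(nrow(trace) > 0)
  keep <- trace$time >= discard
  tt <- trace$time[keep]
  vv <- trace$v[keep]
  up <- which(vv[-1] >= spike_threshold & vv[-length(vv)] < spike_threshold)
  st <- numeric(0)
  for (i in up) {
    # linear interpolation of the crossing time; refractory tie-break
    tc <- tt[i] + (spike_threshold - vv[i]) / (vv[i + 1] - vv[i]) *
      (tt[i + 1] - tt[i])
    if (length(st) == 0 || tc - st[length(st)] >= refractory)
      st <- c(st, tc)
  }
  empty <- list(spike_times = numeric(0), isis = numeric(0), n_bursts = 0L,
                burst_isis = list(), spikes_per_burst = integer(0),
                burst_period = NA_real_, duty_cycle = NA_real_)
  if (length(st) < 2) {
    empty$spike_times <- st
    return(empty)
  }
  isis <- diff(st)
  if (is.null(burst_gap)) burst_gap <- 5 * stats::median(isis)
  brk <- which(isis > burst_gap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(st))
  burst_isis <- lapply(seq_along(starts), function(k) {
    idx <- starts[k]:ends[k]
    if (length(idx) > 1) diff(st[idx]) else numeric(0)
  })
  onset <- st[starts]
  offset <- st[ends]
  list(spike_times = st, isis = isis, n_bursts = length(starts),
       burst_isis = burst_isis,
       spikes_per_burst = ends - starts + 1L,
       burst_period = if (length(onset) > 1) stats::median(diff(onset))
                      else NA_real_,
       duty_cycle = if (length(onset) > 1)
         stats::median((offset - onset)[-length(onset)] / diff(onset))
       else NA_real_)
}
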