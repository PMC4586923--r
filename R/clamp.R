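#' Voltage-clamp step protocol
#'
#' Defines the simulated voltage-clamp measurement: the membrane is held at
#' each potential `v_holds` until equilibrated, then stepped by `delta_v`
#' while the total transmembrane current is recorded. Dynamic currents are
#' extracted in three windows after step onset — within 2 ms (fast), between
#' 10 and 100 ms (slow), and from 1 s to the end (ultraslow).
#'
#' @param v_holds Holding potentials V* in mV.
#' @param delta_v Step size in mV (nonzero; default 1).
#' @param step_duration Post-step recording in ms (> 1000; default 5000 so
#'   the ultraslow window is well covered).
#' @param hold_duration Maximal simulated hold used when equilibrating
#'   numerically, ms (default 60000; the default initialization is the
#'   analytic steady state, which needs no hold).
#' @param dt_fast,dt_slow Sampling steps: `dt_fast` (default 0.05 ms) up to
#'   10 ms after onset, `dt_slow` (default 1 ms) afterwards.
#' @return A `clamp_protocol` list.
#' @export
clamp_protocol <- function(v_holds, delta_v = 1, step_duration = 5000,
                           hold_duration = 60000, dt_fast = 0.05,
                           dt_slow = 1) {
  stopifnot(delta_v != 0, step_duration > 1000)
  structure(list(v_holds = v_holds, delta_v = delta_v,
                 step_duration = step_duration,
                 hold_duration = hold_duration,
                 dt_fast = dt_fast, dt_slow = dt_slow),
            class = "clamp_protocol")
}

clamp_times <- function(protocol) {
  unique(c(seq(0, min(10, protocol$step_duration), by = protocol$dt_fast),
           seq(min(10, protocol$step_duration), protocol$step_duration,
               by = protocol$dt_slow)))
}

#' Run one voltage-clamp step
#'
#' Equilibrates the model at `v_hold` (analytic steady state by default;
#' `equilibrate = "simulate"` integrates the hold and records a convergence
#' flag instead), then clamps the potential at `v_hold + delta_v` and
#' integrates only the gating/calcium subsystem, recording the total
#' transmembrane current. The first recorded sample (t = 0, pre-step gating
#' state at the stepped potential) is the initial current `I_0`: it already
#' contains the instantaneous ohmic jump through open channels, so the
#' extracted fast dynamic current captures gating-mediated change only.
#'
#' @param model A [neuron_model()].
#' @param v_hold Holding potential in mV.
#' @param delta_v Step in mV.
#' @param protocol A [clamp_protocol()] (its `v_holds` is ignored here).
#' @param equilibrate `"analytic"` or `"simulate"`.
#' @return A `dic_trace` data frame of the post-step current (`time`,
#'   `i_total`, states), with attributes `v_hold`, `delta_v`, `flags`.
#' @export
run_clamp_step <- function(model, v_hold, delta_v = NULL, protocol = NULL,
                           equilibrate = c("analytic", "simulate")) {
  equilibrate <- match.arg(equilibrate)
  if (is.null(protocol)) protocol <- clamp_protocol(v_hold)
  if (is.null(delta_v)) delta_v <- protocol$delta_v
  check_v_range(model, c(v_hold, v_hold + delta_v))
  flags <- character(0)
  init <- steady_state(model, v_hold)
  if (equilibrate == "simulate" && length(init) > 0) {
    ht <- seq(0, protocol$hold_duration, by = 10)
    hold <- simulate_clamped(model, v_hold, ht, steady_state(model, v_hold))
    last <- unlist(hold[nrow(hold), state_names(model)])
    dmax <- max(abs(model_derivs(model, v_hold, last)))
    if (dmax > 1e-9)
      flags <- c(flags, sprintf("hold_not_equilibrated(max|dX/dt|=%.2e)", dmax))
    init <- last
  }
  tr <- simulate_clamped(model, v_hold + delta_v, clamp_times(protocol), init)
  attr(tr, "v_hold") <- v_hold
  attr(tr, "delta_v") <- delta_v
  attr(tr, "flags") <- flags
  class(tr) <- c("dic_trace", "data.frame")
  tr
}

#' Extract window currents from a clamp trace
#'
#' Implements the three-window readout of a post-step current trace:
#' `i0` is the first recorded sample; `i_f` the minimum within 2 ms of
#' onset; `i_s` the minimum between 10 and 100 ms (if the minimum sits at
#' the 10 ms boundary — no interior minimum — the amplitude at 10 ms is
#' taken and flagged); `i_u` the minimal amplitude from 1 s to the end.
#' "Minimum" is the minimum of the sampled trace over the stated window.
#' The dynamic currents telescope: `di_f = i_f - i0`, `di_s = i_s - i_f`,
#' `di_u = i_u - i_s`, and the static change `di_static = i_u - i0` equals
#' their sum by construction.
#'
#' For a two-timescale model (no ultraslow designation) the classical
#' two-window readout applies instead (`timescales = 2`): the slow current
#' `i_s` is the final steady-state current and the ultraslow dynamic
#' current is zero by construction.
#'
#' @param trace A current trace: data frame with `time` (ms from step onset)
#'   and `i_total` (uA/cm^2), e.g. from [run_clamp_step()] or imported from
#'   a recording.
#' @param protocol A [clamp_protocol()] (used for validation only).
#' @param timescales `3` (bursting models, default) or `2` (spiking models
#'   without an ultraslow timescale).
#' @return A `clamp_extraction` list: `i0`, `i_f`, `i_s`, `i_u`, `di_f`,
#'   `di_s`, `di_u`, `di_static`, `flags`.
#' @export
extract_clamp <- function(trace, protocol = NULL, timescales = 3) {
  t <- trace$time
  i <- trace$i_total
  if (max(t) < 1000)
    stop("trace shorter than the ultraslow window (needs >= 1000 ms)")
  flags <- attr(trace, "flags")
  if (is.null(flags)) flags <- character(0)
  i0 <- i[1]
  w_f <- which(t > 0 & t <= 2)
  i_f <- min(i[w_f])
  if (timescales == 2) {
    i_s <- i[length(i)]
    i_u <- i_s
    flags <- c(flags, "two_timescale")
    return(structure(list(i0 = i0, i_f = i_f, i_s = i_s, i_u = i_u,
                          di_f = i_f - i0, di_s = i_s - i_f, di_u = 0,
                          di_static = i_u - i0, flags = flags),
                     class = "clamp_extraction"))
  }
  w_s <- which(t >= 10 & t <= 100)
  ks <- w_s[which.min(i[w_s])]
  if (t[ks] <= min(t[w_s]) + 1e-12) {
    # window minimum at the 10 ms boundary: no local minimum, take 10 ms
    i_s <- i[w_s[1]]
    flags <- c(flags, "i_s_fallback_10ms")
  } else i_s <- i[ks]
  w_u <- which(t >= 1000)
  i_u <- min(i[w_u])
  structure(list(i0 = i0, i_f = i_f, i_s = i_s, i_u = i_u,
                 di_f = i_f - i0, di_s = i_s - i_f, di_u = i_u - i_s,
                 di_static = i_u - i0, flags = flags),
            class = "clamp_extraction")
}

#' Measure the dynamic input conductances by simulated voltage clamp
#'
#' Runs the full protocol — one clamp step per holding potential — and
#' converts the extracted dynamic currents to conductances:
#' \eqn{g_j(V^* + \Delta V/2) = -\Delta I_j / \Delta V} for
#' \eqn{j = f, s, u}, plus the static \eqn{g = -\Delta I/\Delta V}. The sign
#' convention matches [dic_curves()], so the two routes are directly
#' comparable.
#'
#' @param model A [neuron_model()].
#' @param protocol A [clamp_protocol()].
#' @param timescales `3` or `2` (see [extract_clamp()]); `NULL` resolves
#'   from the model's timescale designation (2 when there is no ultraslow
#'   reference).
#' @return Data frame with one row per hold: `v` (the midpoint
#'   V* + dV/2), `g_f`, `g_s`, `g_u`, `g_total` (mS/cm^2), and `flags`
#'   (collapsed, `""` if none). Extractions attached as attribute
#'   `extractions`.
#' @export
measure_dics <- function(model, protocol, timescales = NULL) {
  if (is.null(timescales)) {
    tri <- reference_timescales(model)
    timescales <- if (is.null(tri$tau_u)) 2 else 3
  }
  ext <- lapply(protocol$v_holds, function(vh) {
    tr <- run_clamp_step(model, vh, protocol$delta_v, protocol)
    extract_clamp(tr, protocol, timescales = timescales)
  })
  df <- do.call(rbind, lapply(seq_along(ext), function(k) {
    e <- ext[[k]]
    data.frame(v = protocol$v_holds[k] + protocol$delta_v / 2,
               g_f = -e$di_f / protocol$delta_v,
               g_s = -e$di_s / protocol$delta_v,
               g_u = -e$di_u / protocol$delta_v,
               g_total = -e$di_static / protocol$delta_v,
               flags = paste(e$flags, collapse = ";"))
  }))
  attr(df, "extractions") <- ext
  df
}
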