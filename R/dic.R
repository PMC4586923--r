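## Per-variable "pathway" terms of the decomposition.
##
## For each gating pathway X of current i the static input conductance
## receives  S_X(V) = -(dI_i/dX)(dX_inf/dV)  evaluated at gating steady
## state, and each dynamic input conductance receives the share of S_X that
## the timescale weights assign to it. The minus sign implements the
## g = -dI/dV convention: the fast sodium pathway comes out positive
## (regenerative) and the delayed-rectifier pathway negative (restorative).
## Capacitance is factored out so the curves carry mS/cm^2.
##
## A calcium-dependent gate contributes through two pathways: a direct
## voltage pathway weighted at the gate's own time constant, and an indirect
## pathway through Ca_inf(V) weighted at the pool time constant (ultraslow).
##
## Returns a list of terms: list(current, value (vector over v), tau (vector)).
dic_pathways <- function(model, v, ca_ref = NULL, dv = 1e-3) {
  if (is.null(ca_ref)) ca_ref <- resolve_ca_ref(model, "steady")
  ca <- if (!is.null(ca_ref)) ca_ref(v) else NULL
  ca_hi <- if (!is.null(ca_ref)) ca_ref(v + dv) else NULL
  ca_lo <- if (!is.null(ca_ref)) ca_ref(v - dv) else NULL
  tau_ca <- if (!is.null(model$calcium)) model$calcium$tau else NULL
  terms <- list()
  for (cur in model$currents) {
    act <- cur$activation
    inact <- cur$inactivation
    m <- if (is.null(act)) 1 else gate_inf(act, v, ca)
    h <- if (is.null(inact)) 1 else gate_inf(inact, v, ca)
    p <- if (is.null(act)) 0L else act$exponent
    q <- if (is.null(inact)) 0L else inact$exponent
    drive <- v - cur$erev
    for (slot in list(act, inact)) {
      if (is.null(slot)) next
      if (slot$role == "activation") {
        base <- cur$gbar * p * (if (p > 1) m^(p - 1) else 1) *
          (if (q > 0) h^q else 1) * drive
      } else {
        base <- cur$gbar * q * (if (q > 1) h^(q - 1) else 1) *
          (if (p > 0) m^p else 1) * drive
      }
      # direct voltage dependence of the steady state (central difference)
      d_direct <- (gate_inf(slot, v + dv, ca) -
                   gate_inf(slot, v - dv, ca)) / (2 * dv)
      terms[[length(terms) + 1L]] <-
        list(current = cur$name, gate = slot$name,
             value = -base * d_direct, tau = slot$tau(v))
      if (slot$ca_dependent) {
        # indirect dependence through the calcium pool steady state
        d_ca <- (gate_inf(slot, v, ca_hi) -
                 gate_inf(slot, v, ca_lo)) / (2 * dv)
        terms[[length(terms) + 1L]] <-
          list(current = cur$name, gate = paste0(slot$name, ".Ca"),
               value = -base * d_ca, tau = rep_len(tau_ca, length(v)))
      }
    }
  }
  terms
}

#' Dynamic input conductance curves
#'
#' Computes the fast, slow and ultraslow dynamic input conductances
#' \eqn{g_f(V), g_s(V), g_u(V)} and the static input conductance
#' \eqn{g(V) = g_f + g_s + g_u} of a conductance-based model, analytically:
#' each state variable contributes its pathway derivative
#' \eqn{-(\partial I/\partial X_i)(\partial X_{i,\infty}/\partial V)} split
#' across the three timescales by the logarithmic-distance weights of
#' [dic_weights()]. Passive membrane properties (the leak) contribute
#' nothing: their variations are instantaneous compared to gating kinetics.
#' Positive values act as positive (regenerative) feedback in their
#' timescale, negative values as restorative feedback.
#'
#' @param model A [neuron_model()].
#' @param v_grid Potentials in mV (default: working range at 0.1 mV).
#' @param triplet Optional [reference_timescales()]; resolved automatically
#'   otherwise.
#' @param ca_ref Calcium reference `function(v)` for calcium-dependent gates
#'   and the indirect calcium pathway; default: this model's pool
#'   equilibrium `Ca_inf(V)`. Pass another model's reference to freeze the
#'   calcium coupling (the convention of the compensation machinery).
#' @return A `dic_set`: list with `v`, `g_f`, `g_s`, `g_u`, `g_total`, and
#'   `per_channel`, a named list of `cbind(f, s, u)` matrices (one row per
#'   grid point) whose sum over channels reproduces each aggregate curve.
#' @export
dic_curves <- function(model, v_grid = NULL, triplet = NULL, ca_ref = NULL) {
  if (is.null(v_grid))
    v_grid <- seq(model$v_range[1], model$v_range[2], by = 0.1)
  check_v_range(model, v_grid)
  if (is.null(triplet)) triplet <- reference_timescales(model)
  tf <- triplet$tau_f(v_grid)
  ts <- triplet$tau_s(v_grid)
  tu <- if (!is.null(triplet$tau_u)) triplet$tau_u(v_grid) else NULL
  terms <- dic_pathways(model, v_grid, ca_ref = ca_ref)
  zero <- numeric(length(v_grid))
  per <- list()
  for (cur in model$currents)
    per[[cur$name]] <- cbind(f = zero, s = zero, u = zero)
  warn_ca <- FALSE
  for (tm in terms) {
    w <- dic_weights(tm$tau, tf, ts, tu)
    contrib <- cbind(f = w$w_fs * tm$value,
                     s = (w$w_su - w$w_fs) * tm$value,
                     u = (1 - w$w_su) * tm$value)
    per[[tm$current]] <- per[[tm$current]] + contrib
    if (grepl("\\.Ca$", tm$gate) && mean(1 - w$w_su) < 0.8) warn_ca <- TRUE
  }
  if (warn_ca)
    warning("the calcium pool time constant places an appreciable share of ",
            "the calcium pathway outside the ultraslow timescale; the ",
            "decomposition assumes calcium acts ultraslowly")
  g_f <- Reduce(`+`, lapply(per, function(x) x[, "f"]), zero)
  g_s <- Reduce(`+`, lapply(per, function(x) x[, "s"]), zero)
  g_u <- Reduce(`+`, lapply(per, function(x) x[, "u"]), zero)
  structure(list(v = v_grid, g_f = g_f, g_s = g_s, g_u = g_u,
                 g_total = g_f + g_s + g_u, per_channel = per,
                 provenance = triplet$provenance),
            class = "dic_set")
}

#' @export
print.dic_set <- function(x, ...) {
  cat(sprintf("Dynamic input conductances on [%g, %g] mV (%d points)\n",
              min(x$v), max(x$v), length(x$v)))
  for (nm in c("g_f", "g_s", "g_u", "g_total"))
    cat(sprintf("  %-8s in [%8.3f, %8.3f] mS/cm2\n", nm,
                min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}

#' Dynamic input conductances at a single potential
#'
#' @param model A [neuron_model()].
#' @param v Potential in mV.
#' @inheritParams dic_curves
#' @return Named vector `c(g_f, g_s, g_u, g_total)` in mS/cm^2.
#' @export
dic_at <- function(model, v, triplet = NULL, ca_ref = NULL) {
  stopifnot(length(v) == 1L)
  d <- dic_curves(model, v_grid = v, triplet = triplet, ca_ref = ca_ref)
  c(g_f = unname(d$g_f), g_s = unname(d$g_s), g_u = unname(d$g_u),
    g_total = unname(d$g_total))
}

#' Export a DIC set as a data frame
#'
#' @param x A `dic_set`.
#' @param ... Unused.
#' @return Data frame with `v`, the four aggregate curves and one
#'   `<channel>_<timescale>` column per channel per timescale (mS/cm^2).
#' @export
as.data.frame.dic_set <- function(x, ...) {
  df <- data.frame(v = x$v, g_f = x$g_f, g_s = x$g_s, g_u = x$g_u,
                   g_total = x$g_total)
  for (nm in names(x$per_channel))
    for (j in c("f", "s", "u"))
      df[[paste0(nm, "_", j)]] <- x$per_channel[[nm]][, j]
  df
}
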