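#' Sensitivity curves of the dynamic input conductances
#'
#' Derivative of each dynamic input conductance with respect to one
#' channel's maximal conductance, as voltage-dependent curves. For a current
#' \eqn{\bar g_i m^p h^q (V - V_i)} the closed forms are the per-unit
#' pathway terms of the decomposition, e.g.
#' \deqn{\partial g_f/\partial \bar g_i = -\,w_{fs}^{m}\, p\, m^{p-1} h^q
#'   (V - V_i)\, \partial m_\infty/\partial V \;-\; w_{fs}^{h}\, q\, m^p
#'   h^{q-1} (V - V_i)\, \partial h_\infty/\partial V}
#' (minus sign: the `g = -dI/dV` convention), and analogously with
#' \eqn{(w_{su} - w_{fs})} and \eqn{(1 - w_{su})} for the slow and ultraslow
#' curves. The curves do not depend on \eqn{\bar g_i} itself. The frozen-
#' calcium convention applies: the calcium pool steady state of the
#' reference model is treated as fixed, so the indirect dependence of a
#' calcium-gated channel on the calcium conductances is excluded; the
#' calcium-gated channel's own curves do include its ultraslow calcium
#' pathway (they stay exact derivatives at frozen `Ca_inf`).
#'
#' @param model A [neuron_model()].
#' @param current Channel name.
#' @param v_grid Potentials in mV (default: working range at 0.1 mV).
#' @param triplet Optional [reference_timescales()].
#' @param ca_ref Calcium reference function; default the model's own
#'   `Ca_inf(V)`.
#' @return Data frame with columns `v`, `f`, `s`, `u` (dimensionless: mS/cm^2
#'   of conductance per mS/cm^2 of channel density).
#' @export
sensitivity_curves <- function(model, current, v_grid = NULL, triplet = NULL,
                               ca_ref = NULL) {
  if (!current %in% names(model$currents))
    stop("unknown current: '", current, "'")
  if (is.null(v_grid))
    v_grid <- seq(model$v_range[1], model$v_range[2], by = 0.1)
  if (is.null(triplet)) triplet <- reference_timescales(model)
  if (is.null(ca_ref)) ca_ref <- resolve_ca_ref(model, "steady")
  unit <- set_gbar(model, current, 1)
  d <- dic_curves(unit, v_grid, triplet = triplet, ca_ref = ca_ref)
  pc <- d$per_channel[[current]]
  data.frame(v = v_grid, f = pc[, "f"], s = pc[, "s"], u = pc[, "u"])
}

#' Sensitivity table over all channels
#'
#' @inheritParams sensitivity_curves
#' @return Long data frame with columns `v`, `current`, `f`, `s`, `u`.
#' @export
sensitivity_table <- function(model, v_grid = NULL, triplet = NULL,
                              ca_ref = NULL) {
  if (is.null(v_grid))
    v_grid <- seq(model$v_range[1], model$v_range[2], by = 0.1)
  if (is.null(triplet)) triplet <- reference_timescales(model)
  if (is.null(ca_ref)) ca_ref <- resolve_ca_ref(model, "steady")
  do.call(rbind, lapply(names(model$currents), function(nm) {
    s <- sensitivity_curves(model, nm, v_grid, triplet, ca_ref)
    cbind(data.frame(current = nm), s)
  }))
}

#' Sensitivities at the voltage markers, with localization curves
#'
#' Evaluates every channel's sensitivity curves at spike threshold
#' \eqn{V_{th}} and up-state \eqn{V_{osc}}, and normalizes each curve by its
#' maximum absolute value over the grid (range becomes \[-1, 1\]) to sketch
#' the localization of the sensitivity ranges on the voltage axis.
#'
#' @param model A [neuron_model()].
#' @param markers Optional precomputed [voltage_markers()] list.
#' @param v_grid Potentials for the localization curves.
#' @return List with `markers`, `at_markers` (data frame: current,
#'   timescale, value at `v_th`, value at `v_osc`), `localization` (long
#'   data frame of normalized curves) and `flags` (channels whose curve was
#'   identically zero, left unnormalized).
#' @export
sensitivity_at_markers <- function(model, markers = NULL, v_grid = NULL) {
  if (is.null(markers)) markers <- voltage_markers(model)
  if (is.null(v_grid))
    v_grid <- seq(model$v_range[1], model$v_range[2], by = 0.1)
  triplet <- reference_timescales(model)
  ca_ref <- resolve_ca_ref(model, "steady")
  at <- list(); loc <- list(); flags <- character(0)
  for (nm in names(model$currents)) {
    s_th <- sensitivity_curves(model, nm, markers$v_th, triplet, ca_ref)
    s_osc <- sensitivity_curves(model, nm, markers$v_osc, triplet, ca_ref)
    curves <- sensitivity_curves(model, nm, v_grid, triplet, ca_ref)
    for (j in c("f", "s", "u")) {
      at[[length(at) + 1L]] <- data.frame(
        current = nm, timescale = j,
        at_v_th = s_th[[j]], at_v_osc = s_osc[[j]])
      peak <- max(abs(curves[[j]]))
      if (peak == 0) {
        flags <- c(flags, paste0(nm, ":", j))
        norm <- curves[[j]]
      } else norm <- curves[[j]] / peak
      loc[[length(loc) + 1L]] <- data.frame(
        v = v_grid, current = nm, timescale = j, normalized = norm)
    }
  }
  list(markers = markers, at_markers = do.call(rbind, at),
       localization = do.call(rbind, loc), flags = flags)
}

#' Colocalization of two channels' sensitivity curves
#'
#' Scores how well the sensitivity ranges of two channels colocalize on the
#' voltage axis in one timescale. Channels whose sensitivity ranges overlap
#' can compensate for one another in that timescale, regardless of the sign
#' of their contribution (a restorative channel compensates a regenerative
#' one with a mirrored curve).
#'
#' Two scores are available: `"cosine"`, the magnitude of the inner product
#' of the L2-normalized curves (1 = identical localization and shape up to
#' sign), and `"peak"`, minus the distance in mV between the potentials of
#' maximal absolute sensitivity (0 = peaks coincide). The peak score is the
#' sharper localization probe when two candidate curves are both highly
#' similar to the reference.
#'
#' @param model A [neuron_model()].
#' @param current_a,current_b Channel names.
#' @param timescale `"f"`, `"s"` or `"u"`.
#' @param v_grid Potentials for the score.
#' @param method `"cosine"` or `"peak"`.
#' @return A scalar overlap score (higher = more colocalized).
#' @export
overlap_score <- function(model, current_a, current_b, timescale = "s",
                          v_grid = NULL, method = c("cosine", "peak")) {
  method <- match.arg(method)
  if (is.null(v_grid))
    v_grid <- seq(model$v_range[1], model$v_range[2], by = 0.1)
  triplet <- reference_timescales(model)
  ca_ref <- resolve_ca_ref(model, "steady")
  curve <- function(nm)
    sensitivity_curves(model, nm, v_grid, triplet, ca_ref)[[timescale]]
  sa <- curve(current_a)
  sb <- curve(current_b)
  if (method == "cosine") {
    den <- sqrt(sum(sa^2) * sum(sb^2))
    if (den == 0) return(0)
    abs(sum(sa * sb)) / den
  } else {
    -abs(v_grid[which.max(abs(sa))] - v_grid[which.max(abs(sb))])
  }
}

#' Shift a gate's voltage dependence
#'
#' Translates a channel's activation (or inactivation) steady state and time
#' constant by `delta_mv` along the voltage axis (positive = rightward, to
#' more depolarized potentials); a half-activation moves by exactly
#' `delta_mv`. The original model is untouched.
#'
#' @param model A [neuron_model()].
#' @param current Channel name.
#' @param gate `"activation"` or `"inactivation"`.
#' @param delta_mv Shift in mV.
#' @return A new [neuron_model()].
#' @export
shift_activation <- function(model, current,
                             gate = c("activation", "inactivation"),
                             delta_mv) {
  gate <- match.arg(gate)
  if (!current %in% names(model$currents))
    stop("unknown current: '", current, "'")
  if (is.null(model$currents[[current]][[gate]]))
    stop("current '", current, "' has no ", gate, " gate")
  m <- model
  m$currents[[current]][[gate]] <-
    shift_gate(model$currents[[current]][[gate]], delta_mv)
  m
}
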