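#' Ionic current of a conductance-based model
#'
#' Represents a current \eqn{I_i = \bar g_i m^p h^q (V - V_i)} with optional
#' activation gate `m` (exponent p) and inactivation gate `h` (exponent q,
#' `h == 1` when absent).
#'
#' @param name Unique current identifier (e.g. `"Na"`, `"CaS"`, `"Kd"`).
#' @param gbar Maximal conductance in mS/cm^2 (channel density). Must be
#'   non-negative at construction; nonphysiological negative densities only
#'   arise inside compensation results.
#' @param erev Reversal potential in mV.
#' @param activation,inactivation [dic_gate()] objects or `NULL`.
#' @param calcium_carrying Logical; does this current feed the calcium pool?
#' @param polarity `"depolarizing"`, `"repolarizing"`, or `NULL` to infer from
#'   the reversal potential (above -30 mV counts as depolarizing).
#' @param force Allow a negative `gbar` (flagged nonphysiological); used to
#'   inspect compensation solutions, never by the fixtures.
#' @return An object of class `ionic_current`.
#' @export
ionic_current <- function(name, gbar, erev, activation = NULL,
                          inactivation = NULL, calcium_carrying = FALSE,
                          polarity = NULL, force = FALSE) {
  if (gbar < 0 && !force)
    stop("negative maximal conductance for '", name,
         "' (use force = TRUE to build a nonphysiological current)")
  if (!is.null(activation) && activation$role != "activation")
    stop("activation slot of '", name, "' holds a non-activation gate")
  if (!is.null(inactivation) && inactivation$role != "inactivation")
    stop("inactivation slot of '", name, "' holds a non-inactivation gate")
  if (is.null(polarity))
    polarity <- if (erev > -30) "depolarizing" else "repolarizing"
  structure(list(name = name, gbar = gbar, erev = erev,
                 activation = activation, inactivation = inactivation,
                 calcium_carrying = isTRUE(calcium_carrying),
                 polarity = polarity,
                 nonphysiological = gbar < 0),
            class = "ionic_current")
}

#' Intracellular calcium pool
#'
#' First-order pool \eqn{\tau_{Ca}\,\dot{Ca} = -f\,(\sum I_{Ca}) - Ca + Ca_0}
#' integrating the calcium influx carried by the calcium currents. With the
#' sign convention that inward currents are negative, influx raises the
#' concentration. The pool acts as an ultraslow integrator: its time constant
#' should sit at or beyond the slowest gating kinetics of the model.
#'
#' @param tau Pool time constant in ms.
#' @param f Current-to-concentration conversion in uM per (uA/cm^2).
#' @param ca0 Baseline concentration in uM.
#' @return An object of class `calcium_pool`.
#' @export
calcium_pool <- function(tau = 200, f = 0.94, ca0 = 0.05) {
  stopifnot(tau > 0, ca0 >= 0)
  structure(list(tau = tau, f = f, ca0 = ca0), class = "calcium_pool")
}

#' Conductance-based neuron model
#'
#' Membrane equation
#' \eqn{C\,\dot V = -(\sum_i I_i + I_L) + I_{app}} with
#' \eqn{I_L = g_L (V - E_L)} and first-order gating kinetics for every gate.
#'
#' @param currents List of [ionic_current()] objects with unique names.
#' @param leak List `list(g = , erev = )` in mS/cm^2 and mV.
#' @param capacitance Membrane capacitance in uF/cm^2.
#' @param calcium A [calcium_pool()] or `NULL`.
#' @param i_app Applied current density in uA/cm^2.
#' @param v_range Working membrane-potential interval in mV.
#' @param designation Optional explicit timescale designation (see
#'   [reference_timescales()]); fixtures bake in the appropriate one.
#' @return An object of class `neuron_model`.
#' @export
neuron_model <- function(currents, leak = list(g = 0, erev = -50),
                         capacitance = 1, calcium = NULL, i_app = 0,
                         v_range = c(-80, 50), designation = NULL) {
  nm <- vapply(currents, function(cur) cur$name, character(1))
  if (anyDuplicated(nm)) stop("current names must be unique")
  names(currents) <- nm
  needs_ca <- any(vapply(currents, function(cur) {
    (!is.null(cur$activation) && cur$activation$ca_dependent) ||
      (!is.null(cur$inactivation) && cur$inactivation$ca_dependent)
  }, logical(1)))
  if (needs_ca && is.null(calcium))
    stop("a gate depends on calcium but the model has no calcium pool")
  structure(list(currents = currents, leak = leak,
                 capacitance = capacitance, calcium = calcium,
                 i_app = i_app, v_range = v_range,
                 designation = designation),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat("Conductance-based neuron model\n")
  cat(sprintf("  %d ionic currents, C = %g uF/cm2, I_app = %g uA/cm2\n",
              length(x$currents), x$capacitance, x$i_app))
  for (cur in x$currents) {
    gates <- c(if (!is.null(cur$activation))
                 sprintf("m^%d", cur$activation$exponent),
               if (!is.null(cur$inactivation))
                 sprintf("h^%d", cur$inactivation$exponent))
    cat(sprintf("  %-4s gbar = %8.3f mS/cm2  E = %6.1f mV  %s\n",
                cur$name, cur$gbar, cur$erev,
                paste(gates, collapse = " ")))
  }
  cat(sprintf("  leak: g = %g mS/cm2, E = %g mV\n", x$leak$g, x$leak$erev))
  if (!is.null(x$calcium))
    cat(sprintf("  calcium pool: tau = %g ms, f = %g uM.cm2/uA, Ca0 = %g uM\n",
                x$calcium$tau, x$calcium$f, x$calcium$ca0))
  invisible(x)
}

check_v_range <- function(model, v) {
  if (any(v < model$v_range[1] - 1e-9) || any(v > model$v_range[2] + 1e-9))
    stop(sprintf("potential outside the working range [%g, %g] mV",
                 model$v_range[1], model$v_range[2]))
  invisible(v)
}

#' Steady-state calcium concentration
#'
#' Equilibrium of the pool balance equation with the calcium-carrying
#' currents evaluated at gating steady state:
#' \eqn{Ca_\infty(V) = Ca_0 - f \sum I_{Ca,\infty}(V)}. Inherits the maximal
#' conductances of the model instance.
#'
#' @param model A [neuron_model()] with a calcium pool.
#' @param v Membrane potential(s) in mV.
#' @return Concentration(s) in uM (vectorized over `v`).
#' @export
ca_steady <- function(model, v) {
  if (is.null(model$calcium)) stop("model has no calcium pool")
  tot <- 0
  for (cur in model$currents) {
    if (!cur$calcium_carrying) next
    m <- if (is.null(cur$activation)) 1
         else gate_inf(cur$activation, v)^cur$activation$exponent
    h <- if (is.null(cur$inactivation)) 1
         else gate_inf(cur$inactivation, v)^cur$inactivation$exponent
    tot <- tot + cur$gbar * m * h * (v - cur$erev)
  }
  pmax(model$calcium$ca0 - model$calcium$f * tot, 0)
}

## Resolve the calcium reference used by a curve operation:
##  "steady"   - pool equilibrium of this model, Ca_inf(V)
##  "baseline" - pool held at its baseline Ca_0 (ultraslow variable frozen)
##  a function(v) - externally supplied reference (e.g. frozen at another
##                  model's steady state, the compensation convention)
resolve_ca_ref <- function(model, calcium) {
  if (is.null(model$calcium)) return(NULL)
  if (is.function(calcium)) return(calcium)
  calcium <- match.arg(calcium, c("steady", "baseline"))
  if (calcium == "steady") {
    function(v) ca_steady(model, v)
  } else {
    ca0 <- model$calcium$ca0
    function(v) rep_len(ca0, length(v))
  }
}

## Ordered state names: gates as "<current>.m"/"<current>.h", then "Ca".
state_names <- function(model) {
  nm <- character(0)
  for (cur in model$currents) {
    if (!is.null(cur$activation)) nm <- c(nm, paste0(cur$name, ".m"))
    if (!is.null(cur$inactivation)) nm <- c(nm, paste0(cur$name, ".h"))
  }
  if (!is.null(model$calcium)) nm <- c(nm, "Ca")
  nm
}

#' Full steady state of the gating variables and calcium pool
#'
#' Evaluates every gate at \eqn{X_\infty(v)} and the calcium pool at its
#' equilibrium. Idempotent: re-evaluating a steady state changes nothing.
#'
#' @param model A [neuron_model()].
#' @param v Membrane potential in mV, inside the model's working range.
#' @return Named numeric vector over the model's state variables (possibly
#'   empty for a gateless model).
#' @export
steady_state <- function(model, v) {
  stopifnot(length(v) == 1L)
  check_v_range(model, v)
  ca <- if (!is.null(model$calcium)) ca_steady(model, v) else NULL
  st <- numeric(0)
  for (cur in model$currents) {
    if (!is.null(cur$activation))
      st[paste0(cur$name, ".m")] <- gate_inf(cur$activation, v, ca)
    if (!is.null(cur$inactivation))
      st[paste0(cur$name, ".h")] <- gate_inf(cur$inactivation, v, ca)
  }
  if (!is.null(model$calcium)) st["Ca"] <- ca
  st
}

## Instantaneous ionic currents for a given state vector (uA/cm^2).
## Returns a named vector per current plus "leak".
eval_currents <- function(model, v, state) {
  out <- numeric(length(model$currents) + 1L)
  names(out) <- c(names(model$currents), "leak")
  for (cur in model$currents) {
    m <- if (is.null(cur$activation)) 1
         else state[[paste0(cur$name, ".m")]]^cur$activation$exponent
    h <- if (is.null(cur$inactivation)) 1
         else state[[paste0(cur$name, ".h")]]^cur$inactivation$exponent
    out[cur$name] <- cur$gbar * m * h * (v - cur$erev)
  }
  out["leak"] <- model$leak$g * (v - model$leak$erev)
  out
}

#' Static I/V curve
#'
#' Total steady-state membrane current (ionic + leak, excluding the applied
#' current unless `include_i_app`) as a function of clamped potential. Linear
#' in every maximal conductance for a fixed calcium reference. Its zeros
#' (of `I_static - I_app`) are the equilibria of the model.
#'
#' @param model A [neuron_model()].
#' @param v_grid Potentials in mV (non-empty, inside the working range).
#' @param calcium Calcium reference for calcium-dependent gates: `"steady"`
#'   (pool at equilibrium, the default; what a long voltage-clamp step
#'   measures), `"baseline"` (pool frozen at `Ca_0`), or a `function(v)`.
#' @param include_i_app Subtract the applied current (so that zeros of the
#'   returned curve are equilibria)? Default `FALSE`.
#' @param per_channel Return a matrix with one column per current (plus leak)
#'   instead of the total?
#' @return Current density in uA/cm^2, vector over `v_grid` (or matrix).
#' @export
static_iv <- function(model, v_grid, calcium = "steady",
                      include_i_app = FALSE, per_channel = FALSE) {
  if (length(v_grid) == 0) stop("empty potential grid")
  check_v_range(model, v_grid)
  ca_ref <- resolve_ca_ref(model, calcium)
  ca <- if (!is.null(ca_ref)) ca_ref(v_grid) else NULL
  cols <- vapply(model$currents, function(cur) {
    m <- if (is.null(cur$activation)) 1
         else gate_inf(cur$activation, v_grid, ca)^cur$activation$exponent
    h <- if (is.null(cur$inactivation)) 1
         else gate_inf(cur$inactivation, v_grid, ca)^cur$inactivation$exponent
    cur$gbar * m * h * (v_grid - cur$erev)
  }, numeric(length(v_grid)))
  cols <- matrix(cols, nrow = length(v_grid),
                 dimnames = list(NULL, names(model$currents)))
  cols <- cbind(cols, leak = model$leak$g * (v_grid - model$leak$erev))
  tot <- rowSums(cols)
  if (include_i_app) tot <- tot - model$i_app
  if (per_channel) {
    if (include_i_app) cols <- cbind(cols, i_app = -rep(model$i_app, length(v_grid)))
    cols
  } else tot
}

## Net equilibrium current I_app - I_static(V): positive depolarizes.
## Zeros are equilibria; its V-derivative is -dI_static/dV.
net_current_fn <- function(model, calcium = "steady") {
  ca_ref <- resolve_ca_ref(model, calcium)
  function(v) model$i_app - static_iv(model, v, calcium = if (is.null(ca_ref)) "steady" else ca_ref)
}
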