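#' Gating variable of an ionic current
#'
#' A gating variable relaxes with first-order kinetics
#' \eqn{\tau_X(V)\,\dot X = X_\infty(V) - X} toward a voltage-dependent steady
#' state in \[0, 1\]. Activation gates open the channel with depolarization,
#' inactivation gates close it. A gate may additionally depend on the
#' intracellular calcium concentration (e.g. the calcium-activated potassium
#' channel), in which case `inf` takes `(v, ca)`.
#'
#' @param name Short identifier, e.g. `"m"` or `"h"`.
#' @param role `"activation"` or `"inactivation"`.
#' @param exponent Positive integer power with which the gate enters the
#'   current (the `p` of `m^p` or `q` of `h^q`).
#' @param inf Steady-state function of membrane potential in mV (and calcium
#'   in uM if `ca_dependent`), returning a value in \[0, 1\].
#' @param tau Time-constant function of membrane potential, returning ms.
#' @param ca_dependent Logical; does `inf` take a second calcium argument?
#' @return An object of class `dic_gate`.
#' @export
dic_gate <- function(name, role = c("activation", "inactivation"),
                     exponent = 1L, inf, tau, ca_dependent = FALSE) {
  role <- match.arg(role)
  stopifnot(is.function(inf), is.function(tau),
            length(exponent) == 1L, exponent >= 1)
  structure(list(name = name, role = role, exponent = as.integer(exponent),
                 inf = inf, tau = tau, ca_dependent = isTRUE(ca_dependent)),
            class = "dic_gate")
}

## Evaluate a gate's steady state, passing calcium only where it is used.
gate_inf <- function(gate, v, ca = NULL) {
  if (gate$ca_dependent) {
    if (is.null(ca)) stop("gate '", gate$name, "' needs a calcium value")
    gate$inf(v, ca)
  } else {
    gate$inf(v)
  }
}

#' Kinetics function registry
#'
#' Closed functional forms used by the bundled fixtures and by model
#' configuration files. All potentials in mV, all times in ms.
#'
#' * `boltzmann(half, slope)`: \eqn{1/(1+e^{-(V-\mathrm{half})/\mathrm{slope}})};
#'   increasing in V for positive `slope`, decreasing for negative.
#' * `tau_sigmoid(base, amp, half, slope)`:
#'   \eqn{\mathrm{base} + \mathrm{amp}/(1+e^{-(V-\mathrm{half})/\mathrm{slope}})}.
#' * `tau_biexp(base, amp, half1, slope1, half2, slope2)`:
#'   \eqn{\mathrm{base} + \mathrm{amp}/(e^{(V-\mathrm{half1})/\mathrm{slope1}} +
#'   e^{(V-\mathrm{half2})/\mathrm{slope2}})}.
#' * `tau_double_sigmoid(...)`: product of a sigmoid and a shifted sigmoid
#'   (sodium inactivation time constant of the STG model).
#' * `ca_boltzmann(half, slope, kd)`: a Boltzmann in V multiplied by the
#'   saturating calcium factor \eqn{Ca/(Ca + k_d)} (calcium-activated
#'   potassium activation); the returned function takes `(v, ca)`.
#' * `constant(value)`.
#'
#' @param form One of the registry names above.
#' @param params Named list of parameters for the form.
#' @return A function of `v` carrying attributes `form` and `params` so that
#'   it can be serialized back into a configuration file.
#' @export
kinetics_fn <- function(form, params) {
  params <- as.list(params)
  f <- switch(form,
    boltzmann = function(v) {
      1 / (1 + exp(-(v - params$half) / params$slope))
    },
    tau_sigmoid = function(v) {
      params$base + params$amp / (1 + exp(-(v - params$half) / params$slope))
    },
    tau_biexp = function(v) {
      params$base + params$amp /
        (exp((v - params$half1) / params$slope1) +
         exp((v - params$half2) / params$slope2))
    },
    tau_double_sigmoid = function(v) {
      (params$amp / (1 + exp(-(v - params$half1) / params$slope1))) *
        (params$base2 + 1 / (1 + exp((v - params$half2) / params$slope2)))
    },
    ca_boltzmann = function(v, ca) {
      (ca / (ca + params$kd)) /
        (1 + exp(-(v - params$half) / params$slope))
    },
    constant = function(v) rep_len(params$value, length(v)),
    stop("unknown kinetics form: '", form, "'")
  )
  attr(f, "form") <- form
  attr(f, "params") <- params
  f
}

## Translate a gate by delta mV along the voltage axis (both inf and tau).
shift_gate <- function(gate, delta) {
  if (delta == 0) return(gate)
  inf0 <- gate$inf
  tau0 <- gate$tau
  inf <- if (gate$ca_dependent) {
    function(v, ca) inf0(v - delta, ca)
  } else {
    function(v) inf0(v - delta)
  }
  g <- gate
  g$inf <- inf
  g$tau <- function(v) tau0(v - delta)
  # serialization metadata survives a shift of a boltzmann/tau_sigmoid form
  for (slot in c("inf", "tau")) {
    frm <- attr(gate[[slot]], "form")
    prm <- attr(gate[[slot]], "params")
    if (!is.null(frm) && !is.null(prm) && !is.null(prm$half)) {
      prm$half <- prm$half + delta
      attr(g[[slot]], "form") <- frm
      attr(g[[slot]], "params") <- prm
    }
  }
  g
}
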