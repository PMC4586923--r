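the_fixture_cache <- new.env(parent = emptyenv())

stg_spec <- function() {
  if (is.null(the_fixture_cache$stg)) {
    path <- system.file("extdata", "stg_kinetics.yaml", package = "dicurves")
    if (path == "") path <- file.path("inst", "extdata", "stg_kinetics.yaml")
    the_fixture_cache$stg <- yaml::read_yaml(path)
  }
  the_fixture_cache$stg
}

#' STG six-current burster model
#'
#' Builds the stomatogastric-ganglion model cell: sodium (`Na`), T-type and
#' slow calcium (`CaT`, `CaS`), A-type, delayed-rectifier and
#' calcium-activated potassium (`A`, `Kd`, `KCa`), plus leak and an
#' intracellular calcium pool. Reference densities (mS/cm^2): Na 700,
#' CaT 2, CaS 4, A 50, Kd 70, KCa 40; calcium reversal +120 mV; the cell
#' bursts spontaneously at the reference applied current (0 uA/cm^2).
#' The timescale designation is baked in: fast = sodium activation,
#' slow = delayed-rectifier activation, ultraslow = slow-calcium
#' inactivation. Builders are pure: identical arguments give identical
#' models.
#'
#' @param gbar Named vector/list of density overrides, e.g.
#'   `c(CaS = 20)`. Unknown names are an error.
#' @param i_app Applied current override in uA/cm^2.
#' @param v_ca Calcium reversal override in mV.
#' @return A [neuron_model()].
#' @export
make_stg <- function(gbar = NULL, i_app = NULL, v_ca = NULL) {
  spec <- stg_spec()
  model <- model_from_list(spec)
  if (!is.null(gbar)) {
    gbar <- unlist(gbar)
    bad <- setdiff(names(gbar), names(model$currents))
    if (length(bad))
      stop("unknown conductance override(s): ",
           paste0("'", bad, "'", collapse = ", "),
           " (available: ", paste(names(model$currents), collapse = ", "), ")")
    for (nm in names(gbar)) model <- set_gbar(model, nm, unname(gbar[nm]))
  }
  if (!is.null(i_app)) model$i_app <- i_app
  if (!is.null(v_ca))
    for (nm in names(model$currents))
      if (model$currents[[nm]]$calcium_carrying)
        model$currents[[nm]]$erev <- v_ca
  model
}

#' Classical Hodgkin-Huxley squid-axon model
#'
#' Canonical kinetics (modern sign convention, resting potential near
#' -65 mV): `gNa = 120`, `gK = 36`, `gL = 0.3` mS/cm^2, `ENa = 50`,
#' `EK = -77`, `EL = -54.4` mV, C = 1 uF/cm^2. A two-timescale model: the
#' designation is fast = sodium activation, slow = potassium activation
#' (sodium inactivation is weighted between them); there is no ultraslow
#' reference, so the ultraslow conductance vanishes identically.
#'
#' @param gbar Named overrides among `Na`, `K`.
#' @param i_app Applied current in uA/cm^2.
#' @return A [neuron_model()].
#' @export
make_hh <- function(gbar = NULL, i_app = 0) {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2),
                                 x / (exp(x / y) - 1))
  a_m <- function(v) 0.1 * vtrap(-(v + 40), 10)
  b_m <- function(v) 4 * exp(-(v + 65) / 18)
  a_h <- function(v) 0.07 * exp(-(v + 65) / 20)
  b_h <- function(v) 1 / (1 + exp(-(v + 35) / 10))
  a_n <- function(v) 0.01 * vtrap(-(v + 55), 10)
  b_n <- function(v) 0.125 * exp(-(v + 65) / 80)
  g <- c(Na = 120, K = 36)
  if (!is.null(gbar)) {
    gbar <- unlist(gbar)
    bad <- setdiff(names(gbar), names(g))
    if (length(bad)) stop("unknown conductance override(s): ",
                          paste(bad, collapse = ", "))
    g[names(gbar)] <- gbar
  }
  na <- ionic_current("Na", g[["Na"]], 50,
    activation = dic_gate("m", "activation", 3,
      inf = function(v) a_m(v) / (a_m(v) + b_m(v)),
      tau = function(v) 1 / (a_m(v) + b_m(v))),
    inactivation = dic_gate("h", "inactivation", 1,
      inf = function(v) a_h(v) / (a_h(v) + b_h(v)),
      tau = function(v) 1 / (a_h(v) + b_h(v))))
  k <- ionic_current("K", g[["K"]], -77,
    activation = dic_gate("m", "activation", 4,
      inf = function(v) a_n(v) / (a_n(v) + b_n(v)),
      tau = function(v) 1 / (a_n(v) + b_n(v))))
  neuron_model(list(na, k), leak = list(g = 0.3, erev = -54.4),
               capacitance = 1, i_app = i_app, v_range = c(-90, 50),
               designation = list(fast = "Na.m", slow = "K.m"))
}

#' Analytic toy models
#'
#' Small models with closed-form ground truth, used as oracles:
#'
#' * `"passive"`: leak only (`g_leak`, `e_leak`); no gating.
#' * `"one_gate"`: a single current with one first-order activation gate of
#'   constant time constant `tau` (exponent 1). Its clamp response is a
#'   mono-exponential with that time constant; its conductance
#'   decomposition lives wholly in the timescale its `tau` selects.
#' * `"fast_pair"`: one depolarizing and one repolarizing current with
#'   constant-time-constant activation gates (`tau_dep`, `tau_rep`); the
#'   minimal model with a resolvable fast/slow designation.
#'
#' @param type Toy name.
#' @param ... Parameters; see details above. Common: `gbar`, `erev`,
#'   `half`, `slope` (Boltzmann activation), `g_leak`, `e_leak`.
#' @return A [neuron_model()].
#' @export
make_toy <- function(type = c("passive", "one_gate", "fast_pair"), ...) {
  type <- match.arg(type)
  p <- list(...)
  gv <- function(nm, default) if (is.null(p[[nm]])) default else p[[nm]]
  switch(type,
    passive = neuron_model(
      list(), leak = list(g = gv("g_leak", 0.1), erev = gv("e_leak", -50)),
      i_app = gv("i_app", 0)),
    one_gate = {
      tau <- gv("tau", 50)
      cur <- ionic_current(
        "X", gv("gbar", 1), gv("erev", 0),
        activation = dic_gate("m", "activation", gv("exponent", 1),
          inf = kinetics_fn("boltzmann",
                            list(half = gv("half", -40),
                                 slope = gv("slope", 10))),
          tau = kinetics_fn("constant", list(value = tau))))
      neuron_model(list(cur),
                   leak = list(g = gv("g_leak", 0.1),
                               erev = gv("e_leak", -50)),
                   i_app = gv("i_app", 0),
                   designation = list(fast = "X.m", slow = "X.m"))
    },
    fast_pair = {
      dep <- ionic_current(
        "dep", gv("gbar_dep", 5), gv("erev_dep", 50),
        activation = dic_gate("m", "activation", 1,
          inf = kinetics_fn("boltzmann",
                            list(half = gv("half_dep", -40), slope = 8)),
          tau = kinetics_fn("constant",
                            list(value = gv("tau_dep", 0.5)))))
      rep_ <- ionic_current(
        "rep", gv("gbar_rep", 5), gv("erev_rep", -80),
        activation = dic_gate("m", "activation", 1,
          inf = kinetics_fn("boltzmann",
                            list(half = gv("half_rep", -30), slope = 8)),
          tau = kinetics_fn("constant",
                            list(value = gv("tau_rep", 20)))))
      neuron_model(list(dep, rep_),
                   leak = list(g = gv("g_leak", 0.1),
                               erev = gv("e_leak", -50)),
                   i_app = gv("i_app", 0))
    })
}

#' Fixture catalog
#'
#' @param name Fixture name: `"stg"`, `"hh"`, or a [make_toy()] type.
#' @param gbar,i_app Overrides passed through to the builder.
#' @return A [neuron_model()].
#' @export
make_fixture <- function(name, gbar = NULL, i_app = NULL) {
  switch(name,
    stg = make_stg(gbar = gbar, i_app = i_app),
    hh = make_hh(gbar = gbar, i_app = i_app %||% 0),
    passive = ,
    one_gate = ,
    fast_pair = make_toy(name),
    stop("unknown fixture '", name, "' (available: stg, hh, passive, ",
         "one_gate, fast_pair)"))
}
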