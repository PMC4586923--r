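#' Reference timescales of a neuron model
#'
#' Identifies the three reference time constants of the timescale
#' decomposition: the fast one (\eqn{\tau_f}) is the activation time constant
#' of the fastest depolarizing current, the slow one (\eqn{\tau_s}) the
#' activation time constant of the fastest repolarizing current (whose
#' kinetics set the upper frequency limit of fast spiking), and the ultraslow
#' one (\eqn{\tau_u}) the time constant of the slowest gating variable —
#' provided it is separated from the slow timescale; otherwise the model is
#' treated as a two-timescale (spiking, non-bursting) model and \eqn{\tau_u}
#' is absent.
#'
#' @param model A [neuron_model()].
#' @param designation `"auto"`, or an explicit list with entries `fast`,
#'   `slow` and optionally `ultraslow`, each a string `"current.m"`,
#'   `"current.h"` or `"Ca"`. A model built with a baked-in designation
#'   (the fixtures) uses it unless one is passed here.
#' @param separation Minimal ratio (geometric mean over the working range)
#'   between the slowest variable and the slow reference for an automatic
#'   ultraslow designation; default 5.
#' @return An object of class `timescale_triplet`: functions `tau_f`,
#'   `tau_s`, `tau_u` (`NULL` in two-timescale mode) of V and a `provenance`
#'   character vector.
#' @export
reference_timescales <- function(model, designation = NULL, separation = 5) {
  if (is.null(designation)) designation <- model$designation
  if (is.null(designation)) designation <- "auto"
  vars <- model_variables(model)
  if (identical(designation, "auto")) {
    designation <- auto_designation(model, vars, separation)
  } else {
    stopifnot(is.list(designation), !is.null(designation$fast),
              !is.null(designation$slow))
  }
  pick <- function(id) {
    if (is.null(id)) return(NULL)
    if (!id %in% names(vars))
      stop("unknown state variable in designation: '", id, "'")
    vars[[id]]$tau
  }
  tri <- structure(list(tau_f = pick(designation$fast),
                        tau_s = pick(designation$slow),
                        tau_u = pick(designation$ultraslow),
                        provenance = c(fast = designation$fast,
                                       slow = designation$slow,
                                       ultraslow = if (is.null(designation$ultraslow))
                                         NA_character_ else designation$ultraslow)),
                   class = "timescale_triplet")
  check_triplet_order(tri, model$v_range)
  tri
}

## All state variables with their tau functions and metadata.
model_variables <- function(model) {
  vars <- list()
  for (cur in model$currents) {
    if (!is.null(cur$activation))
      vars[[paste0(cur$name, ".m")]] <-
        list(tau = cur$activation$tau, current = cur$name,
             role = "activation", polarity = cur$polarity)
    if (!is.null(cur$inactivation))
      vars[[paste0(cur$name, ".h")]] <-
        list(tau = cur$inactivation$tau, current = cur$name,
             role = "inactivation", polarity = cur$polarity)
  }
  if (!is.null(model$calcium)) {
    tau_ca <- model$calcium$tau
    vars[["Ca"]] <- list(tau = function(v) rep_len(tau_ca, length(v)),
                         current = NA, role = "calcium", polarity = NA)
  }
  vars
}

auto_designation <- function(model, vars, separation) {
  vgrid <- seq(model$v_range[1], model$v_range[2], length.out = 101)
  geo <- vapply(vars, function(vr) exp(mean(log(vr$tau(vgrid)))), numeric(1))
  is_act <- vapply(vars, function(vr) identical(vr$role, "activation"),
                   logical(1))
  dep <- is_act & vapply(vars, function(vr)
    identical(vr$polarity, "depolarizing"), logical(1))
  rep_ <- is_act & vapply(vars, function(vr)
    identical(vr$polarity, "repolarizing"), logical(1))
  if (!any(dep) || !any(rep_))
    stop("automatic designation needs at least one gated depolarizing and ",
         "one gated repolarizing current; pass an explicit designation")
  fast <- names(vars)[dep][which.min(geo[dep])]
  slow <- names(vars)[rep_][which.min(geo[rep_])]
  # slowest gating variable (the calcium pool is an integrator, not a gate)
  gates <- names(vars)[names(vars) != "Ca"]
  slowest <- gates[which.max(geo[gates])]
  ultraslow <- if (geo[slowest] / geo[slow] >= separation &&
                   !identical(slowest, slow)) slowest else NULL
  list(fast = fast, slow = slow, ultraslow = ultraslow)
}

## tau_f <= tau_s <= tau_u must hold across the range; reordering would
## silently change the meaning of the decomposition, so fail loudly.
check_triplet_order <- function(tri, v_range, n = 201) {
  v <- seq(v_range[1], v_range[2], length.out = n)
  tf <- tri$tau_f(v)
  ts <- tri$tau_s(v)
  if (any(tf > ts * (1 + 1e-12)))
    stop("timescale ordering violated: tau_f > tau_s at some potentials")
  if (!is.null(tri$tau_u)) {
    tu <- tri$tau_u(v)
    if (any(ts > tu * (1 + 1e-12)))
      stop("timescale ordering violated: tau_s > tau_u at some potentials")
  }
  invisible(tri)
}

#' Timescale weights of a gating variable
#'
#' Splits the influence of a variable with time constant `tau_x` across the
#' fast/slow/ultraslow timescales by logarithmic distance to the reference
#' time constants: piecewise log-linear interpolation clamped to \[0, 1\],
#' \eqn{w_{fs} = (\ln\tau_s - \ln\tau_x)/(\ln\tau_s - \ln\tau_f)} for
#' \eqn{\tau_f < \tau_x < \tau_s} (1 below, 0 above), and analogously
#' \eqn{w_{su}} on \eqn{(\tau_s, \tau_u)}. The three shares
#' \eqn{w_{fs},\; w_{su}-w_{fs},\; 1-w_{su}} are a non-negative partition of
#' unity. Without an ultraslow reference, \eqn{w_{su} = 1} identically and
#' the ultraslow share vanishes.
#'
#' @param tau_x Variable time constant(s), ms (> 0).
#' @param tau_f,tau_s,tau_u Reference time constants at the same potentials;
#'   `tau_u = NULL` for two-timescale models.
#' @return List with vectors `w_fs` and `w_su` in \[0, 1\],
#'   `w_fs <= w_su`.
#' @export
dic_weights <- function(tau_x, tau_f, tau_s, tau_u = NULL) {
  if (any(tau_x <= 0) || any(tau_f <= 0) || any(tau_s <= 0) ||
      (!is.null(tau_u) && any(tau_u <= 0)))
    stop("time constants must be positive")
  log_interp <- function(tx, tlo, thi) {
    # 1 at tx <= tlo, 0 at tx >= thi, log-linear between; sharp clamping
    n <- max(length(tx), length(tlo), length(thi))
    tx <- rep_len(tx, n)
    tlo <- rep_len(tlo, n)
    thi <- rep_len(thi, n)
    w <- ifelse(thi > tlo,
                (log(thi) - log(tx)) / (log(thi) - log(tlo)),
                ifelse(tx <= tlo, 1, 0))
    pmin(pmax(w, 0), 1)
  }
  w_fs <- log_interp(tau_x, tau_f, tau_s)
  w_su <- if (is.null(tau_u)) rep_len(1, length(w_fs))
          else log_interp(tau_x, tau_s, tau_u)
  list(w_fs = w_fs, w_su = pmax(w_su, w_fs))
}

#' Weight curves of every state variable
#'
#' Tabulates `w_fs` and `w_su` for each state variable of a model over a
#' potential grid (exportable view of the decomposition).
#'
#' @param model A [neuron_model()].
#' @param v_grid Potentials in mV.
#' @param triplet Optional precomputed [reference_timescales()].
#' @return Data frame with columns `v`, `variable`, `tau`, `w_fs`, `w_su`.
#' @export
weight_table <- function(model, v_grid, triplet = NULL) {
  if (is.null(triplet)) triplet <- reference_timescales(model)
  vars <- model_variables(model)
  tf <- triplet$tau_f(v_grid)
  ts <- triplet$tau_s(v_grid)
  tu <- if (!is.null(triplet$tau_u)) triplet$tau_u(v_grid) else NULL
  do.call(rbind, lapply(names(vars), function(nm) {
    tx <- vars[[nm]]$tau(v_grid)
    w <- dic_weights(tx, tf, ts, tu)
    data.frame(v = v_grid, variable = nm, tau = tx,
               w_fs = w$w_fs, w_su = w$w_su)
  }))
}
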