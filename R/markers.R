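## Roots of a scalar curve on a bracketing grid, refined by uniroot.
curve_roots <- function(f, v_range, grid_step = 0.1, tol = 1e-10) {
  v <- seq(v_range[1], v_range[2], by = grid_step)
  y <- f(v)
  sc <- which(y[-1] * y[-length(y)] <= 0 & y[-length(y)] != 0)
  roots <- vapply(sc, function(i)
    stats::uniroot(f, c(v[i], v[i + 1]), tol = tol)$root, numeric(1))
  exact <- v[y == 0]
  sort(unique(c(roots, exact)))
}

#' Up-state potential from a current-voltage curve
#'
#' Returns the most depolarized zero of a net-current curve (root
#' refinement, not a grid pick).
#'
#' @param f Function of V returning net current (positive depolarizing).
#' @param v_range Search interval in mV.
#' @param grid_step Bracketing grid step in mV.
#' @return The largest root, refined below 1e-4 mV.
#' @export
find_upstate_curve <- function(f, v_range, grid_step = 0.1) {
  r <- curve_roots(f, v_range, grid_step)
  if (length(r) == 0)
    stop("no zero of the I/V curve in the working range")
  max(r)
}

#' Up-state potential of a neuron model
#'
#' The up-state \eqn{V_{osc}} is the most depolarized zero of the
#' steady-state I/V curve at the model's applied current: the unstable
#' steady state around which intra-burst oscillations occur. Because those
#' oscillations are too fast to recruit the ultraslow feedback, the curve is
#' evaluated with the calcium pool held at its baseline concentration by
#' default (`calcium = "steady"` gives the fully equilibrated curve
#' instead).
#'
#' @param model A [neuron_model()].
#' @param calcium Calcium reference for the I/V curve (see [static_iv()]);
#'   default `"baseline"`.
#' @param grid_step Bracketing grid step in mV.
#' @return `v_osc` in mV.
#' @export
find_upstate <- function(model, calcium = "baseline", grid_step = 0.1) {
  f <- net_current_fn(model, calcium = calcium)
  find_upstate_curve(f, model$v_range, grid_step)
}

#' Spike-threshold potential from a one-parameter family of I/V curves
#'
#' Locates a codimension-one degenerate equilibrium of a family of
#' net-current curves \eqn{F(V; \alpha)}: the point where
#' \eqn{F(V;\alpha) = 0} and \eqn{\partial F/\partial V(V;\alpha) = 0}
#' simultaneously — two equilibria collide as the parameter is varied.
#'
#' @param f Function `(v, alpha)` returning net current (vectorized in `v`).
#' @param v_range Search interval in mV.
#' @param alpha_range Parameter search interval.
#' @param grid_step Voltage bracketing step in mV.
#' @param n_alpha Number of points of the coarse parameter scan.
#' @return List `v` (the degenerate potential, refined to ~1e-3 mV),
#'   `alpha` (the critical parameter value), and `residuals`
#'   (`c(F, dF/dV)` at the solution).
#' @export
find_threshold_curve <- function(f, v_range, alpha_range = c(0, 10),
                                 grid_step = 0.1, n_alpha = 81) {
  nroots <- function(a) length(curve_roots(function(v) f(v, a), v_range,
                                           grid_step, tol = 1e-8))
  alphas <- seq(alpha_range[1], alpha_range[2], length.out = n_alpha)
  counts <- vapply(alphas, nroots, numeric(1))
  jump <- which(diff(counts) != 0)
  if (length(jump) == 0)
    stop("no degenerate equilibrium: the equilibrium count never changes ",
         "over the parameter interval [", alpha_range[1], ", ",
         alpha_range[2], "]")
  # bisect the first transition; keep 'lo' on the side with more equilibria
  i <- jump[1]
  if (counts[i] > counts[i + 1]) {
    lo <- alphas[i]; hi <- alphas[i + 1]
  } else {
    lo <- alphas[i + 1]; hi <- alphas[i]
  }
  n_lo <- nroots(lo)
  while (abs(hi - lo) > 1e-9) {
    mid <- (lo + hi) / 2
    if (nroots(mid) == n_lo) lo <- mid else hi <- mid
  }
  r_lo <- curve_roots(function(v) f(v, lo), v_range, grid_step, tol = 1e-10)
  r_hi <- curve_roots(function(v) f(v, hi), v_range, grid_step, tol = 1e-10)
  # the colliding pair: roots present on the 'more roots' side whose
  # counterpart vanished on the other side
  gone <- if (length(r_hi) == 0) r_lo else
    r_lo[vapply(r_lo, function(r) min(abs(r - r_hi)) > 10 * grid_step,
                logical(1))]
  v0 <- if (length(gone) >= 1) mean(gone) else mean(r_lo)
  # Newton refinement of (F, dF/dV) = 0 in (v, alpha)
  x <- c(v0, (lo + hi) / 2)
  dv <- 1e-4
  g <- function(x) {
    c(f(x[1], x[2]),
      (f(x[1] + dv, x[2]) - f(x[1] - dv, x[2])) / (2 * dv))
  }
  for (iter in 1:50) {
    gv <- g(x)
    if (max(abs(gv)) < 1e-10) break
    da <- max(abs(x[2]) * 1e-6, 1e-8)
    J <- cbind((g(c(x[1] + dv, x[2])) - g(c(x[1] - dv, x[2]))) / (2 * dv),
               (g(c(x[1], x[2] + da)) - g(c(x[1], x[2] - da))) / (2 * da))
    step <- tryCatch(solve(J, gv), error = function(e) NULL)
    if (is.null(step)) break
    step <- pmin(pmax(step, -2), 2)  # damped
    x <- x - step
  }
  res <- g(x)
  if (max(abs(res)) > 1e-6)
    stop(sprintf(paste0("degenerate-equilibrium refinement did not converge ",
                        "(|F| = %.2e, |dF/dV| = %.2e at V = %.3f)"),
                 abs(res[1]), abs(res[2]), x[1]))
  list(v = x[1], alpha = x[2], residuals = res)
}

#' Spike-threshold potential of a neuron model
#'
#' The spike threshold \eqn{V_{th}} is the potential of maximal sensitivity,
#' where a steady state of the model sits exactly at threshold (a
#' transcritical point of the slow-fast excitability structure). It is
#' located by scaling the maximal conductance of a calcium current until the
#' steady-state I/V relation develops a degenerate (double) zero, and
#' returning that potential. As for [find_upstate()], the I/V curve holds
#' the calcium pool at baseline by default. The applied current is held at
#' the model's reference value during the sweep.
#'
#' @param model A [neuron_model()].
#' @param vary Name of the calcium-carrying current whose density is scaled;
#'   default `"CaS"` if present, else the first calcium-carrying current.
#' @param alpha_range Scaling interval searched (1 = reference density).
#' @param calcium Calcium reference for the I/V curves (default
#'   `"baseline"`).
#' @param grid_step Voltage bracketing step in mV.
#' @return `v_th` in mV, with attributes `alpha` (critical scaling) and
#'   `vary` (the scaled current).
#' @export
find_threshold <- function(model, vary = NULL, alpha_range = c(0, 10),
                           calcium = "baseline", grid_step = 0.1) {
  ca_names <- names(model$currents)[vapply(model$currents,
    function(cur) cur$calcium_carrying, logical(1))]
  if (is.null(vary))
    vary <- if ("CaS" %in% ca_names) "CaS" else ca_names[1]
  if (length(vary) == 0 || is.na(vary) || !vary %in% names(model$currents))
    stop("no calcium-carrying current available to vary; the model has no ",
         "detectable excitability threshold of this type")
  if (!model$currents[[vary]]$calcium_carrying)
    stop("'", vary, "' is not calcium-carrying")
  gbar0 <- model$currents[[vary]]$gbar
  fam <- function(v, a) {
    m <- set_gbar(model, vary, a * gbar0)
    net_current_fn(m, calcium = calcium)(v)
  }
  sol <- find_threshold_curve(fam, model$v_range, alpha_range, grid_step)
  structure(sol$v, alpha = sol$alpha, vary = vary,
            residuals = sol$residuals)
}

#' Both voltage markers of a model
#'
#' @param model A [neuron_model()].
#' @param vary Calcium current scaled for the threshold search.
#' @param calcium Calcium reference for the I/V curves.
#' @return List with `v_th`, `v_osc`, and `meta` (varied current, critical
#'   scaling, residuals).
#' @export
voltage_markers <- function(model, vary = NULL, calcium = "baseline") {
  v_th <- find_threshold(model, vary = vary, calcium = calcium)
  v_osc <- find_upstate(model, calcium = calcium)
  list(v_th = as.numeric(v_th), v_osc = v_osc,
       meta = list(vary = attr(v_th, "vary"),
                   alpha_critical = attr(v_th, "alpha"),
                   residuals = attr(v_th, "residuals")))
}

## Replace one maximal conductance, returning a new model (pure).
set_gbar <- function(model, current, gbar, force = TRUE) {
  if (!current %in% names(model$currents))
    stop("unknown current: '", current, "'")
  m <- model
  m$currents[[current]]$gbar <- gbar
  m$currents[[current]]$nonphysiological <- gbar < 0
  m
}
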