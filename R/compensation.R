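#' Compensation targets from a reference model
#'
#' Fixes the four quantities that the compensation mechanism maintains:
#' the slow conductance at spike threshold and at up-state
#' \eqn{g_s^*(V_{th}), g_s^*(V_{osc})}, the ultraslow conductance at
#' threshold \eqn{g_u^*(V_{th})}, and the net static current at threshold
#' \eqn{I^*_{static}(V_{th}) = I_{app} - I_{static}(V_{th})}. The markers
#' and the calcium reference are computed once, on the reference model, and
#' held fixed across perturbations.
#'
#' @param model The reference [neuron_model()].
#' @param markers Optional precomputed [voltage_markers()].
#' @return A `compensation_targets` list: `gs_th`, `gs_osc`, `gu_th`,
#'   `istatic_th`, `v_th`, `v_osc`, the frozen calcium reference `ca_ref`,
#'   the frozen `triplet`, and the reference values of the compensating
#'   parameters.
#' @export
make_targets <- function(model, markers = NULL) {
  if (is.null(markers)) markers <- voltage_markers(model)
  ca_ref <- resolve_ca_ref(model, "steady")
  triplet <- reference_timescales(model)
  d_th <- dic_at(model, markers$v_th, triplet = triplet, ca_ref = ca_ref)
  d_osc <- dic_at(model, markers$v_osc, triplet = triplet, ca_ref = ca_ref)
  ist <- model$i_app - static_iv(model, markers$v_th,
                                 calcium = if (is.null(ca_ref)) "steady" else ca_ref)
  structure(list(gs_th = unname(d_th["g_s"]), gs_osc = unname(d_osc["g_s"]),
                 gu_th = unname(d_th["g_u"]),
                 istatic_th = unname(ist),
                 v_th = markers$v_th, v_osc = markers$v_osc,
                 ca_ref = ca_ref, triplet = triplet,
                 reference = c(i_app = model$i_app,
                               vapply(model$currents, function(cur) cur$gbar,
                                      numeric(1)))),
            class = "compensation_targets")
}

## Per-unit sensitivity values of the four preserved quantities for one
## channel: rows (gs_th, gs_osc, gu_th, istatic_th). The static row is
## d(I_app - I_static)/d gbar = -(per-unit steady current).
quantity_column <- function(model, current, targets) {
  s_th <- sensitivity_curves(model, current, targets$v_th,
                             triplet = targets$triplet,
                             ca_ref = targets$ca_ref)
  s_osc <- sensitivity_curves(model, current, targets$v_osc,
                              triplet = targets$triplet,
                              ca_ref = targets$ca_ref)
  unit <- set_gbar(model, current, 1)
  per_unit_i <- static_iv(unit, targets$v_th,
                          calcium = if (is.null(targets$ca_ref)) "steady"
                                    else targets$ca_ref,
                          per_channel = TRUE)[, current]
  c(gs_th = s_th$s, gs_osc = s_osc$s, gu_th = s_th$u,
    istatic_th = -unname(per_unit_i))
}

#' Solve the linear compensation problem for one perturbed calcium density
#'
#' Given a perturbed calcium maximal conductance, finds the applied current
#' and the potassium densities \eqn{(I_{app}, \bar g_{K,d}, \bar g_A,
#' \bar g_{K,Ca})} that keep the four target quantities at their reference
#' values, by solving the 4x4 linear system \eqn{Ax = b}: `A` holds the
#' sensitivity values of the compensating parameters at the markers, `b` the
#' targets minus the contributions of the fixed channels (sodium, both
#' calcium channels at their current densities, and the leak). The linearity
#' of the dynamic input conductances in the maximal conductances (at frozen
#' calcium reference) is used exactly, not re-fit. Sodium is not part of the
#' compensating set because the calcium channels barely touch the fast
#' timescale. Negative solved conductances are returned (they are a finding,
#' not an error) but flagged nonphysiological.
#'
#' @param model The reference [neuron_model()].
#' @param perturbed Name of the perturbed calcium current.
#' @param new_gbar Its new density in mS/cm^2.
#' @param targets A [make_targets()] result (computed from `model` if
#'   missing).
#' @param compensators Compensating conductances; default
#'   `c("Kd", "A", "KCa")`.
#' @param use_iapp Include the applied current as fourth unknown and the
#'   static-current row (default). `FALSE` drops both (3x3 variant).
#' @return A `compensation_result`: `x` (named solution), `perturbation`,
#'   `residuals` (targets re-evaluated through the conductance machinery at
#'   the frozen calcium reference, minus targets), `residuals_full` (same
#'   with the perturbed model's own calcium equilibrium: the error incurred
#'   by the frozen-calcium convention), `condition` (condition number of
#'   `A`), `nonphysiological` flag, and `model` (the compensated model).
#' @export
compensate <- function(model, perturbed, new_gbar, targets = NULL,
                       compensators = c("Kd", "A", "KCa"),
                       use_iapp = TRUE) {
  if (!perturbed %in% names(model$currents))
    stop("unknown current: '", perturbed, "'")
  if (is.null(targets)) targets <- make_targets(model)
  if (any(!compensators %in% names(model$currents)))
    stop("unknown compensating current(s)")
  pm <- set_gbar(model, perturbed, new_gbar)
  rows <- if (use_iapp) c("gs_th", "gs_osc", "gu_th", "istatic_th")
          else c("gs_th", "gs_osc", "gu_th")
  cols <- lapply(compensators, function(nm)
    quantity_column(model, nm, targets)[rows])
  A <- do.call(cbind, cols)
  colnames(A) <- compensators
  if (use_iapp) A <- cbind(i_app = c(0, 0, 0, 1), A)
  rownames(A) <- rows
  fixed <- setdiff(names(model$currents), compensators)
  b <- unlist(targets[c("gs_th", "gs_osc", "gu_th", "istatic_th")])[rows]
  for (nm in fixed) {
    g_nm <- if (nm == perturbed) new_gbar else model$currents[[nm]]$gbar
    b <- b - g_nm * quantity_column(model, nm, targets)[rows]
  }
  # leak enters only the static row (it carries no gating)
  if (use_iapp)
    b["istatic_th"] <- b["istatic_th"] +
      model$leak$g * (targets$v_th - model$leak$erev)
  cond <- kappa(A, exact = TRUE)
  if (cond > 1e10)
    stop(sprintf("compensation system is singular or ill-conditioned (condition number %.3g)",
                 cond))
  x <- solve(A, b)
  names(x) <- colnames(A)
  # rebuild the compensated model and close the loop
  cm <- pm
  for (nm in compensators) cm <- set_gbar(cm, nm, unname(x[nm]))
  if (use_iapp) cm$i_app <- unname(x["i_app"])
  resid <- eval_quantities(cm, targets, targets$ca_ref) -
    unlist(targets[c("gs_th", "gs_osc", "gu_th", "istatic_th")])
  resid_full <- eval_quantities(cm, targets, resolve_ca_ref(cm, "steady")) -
    unlist(targets[c("gs_th", "gs_osc", "gu_th", "istatic_th")])
  structure(list(x = x,
                 perturbation = list(current = perturbed,
                                     new_gbar = new_gbar,
                                     reference_gbar =
                                       model$currents[[perturbed]]$gbar),
                 residuals = resid, residuals_full = resid_full,
                 condition = cond,
                 nonphysiological = any(x[setdiff(names(x), "i_app")] < 0),
                 model = cm),
            class = "compensation_result")
}

## The four preserved quantities of a model at fixed markers and calcium ref.
eval_quantities <- function(model, targets, ca_ref) {
  d_th <- dic_at(model, targets$v_th, triplet = targets$triplet,
                 ca_ref = ca_ref)
  d_osc <- dic_at(model, targets$v_osc, triplet = targets$triplet,
                  ca_ref = ca_ref)
  ist <- model$i_app - static_iv(model, targets$v_th,
                                 calcium = if (is.null(ca_ref)) "steady"
                                           else ca_ref)
  c(gs_th = unname(d_th["g_s"]), gs_osc = unname(d_osc["g_s"]),
    gu_th = unname(d_th["g_u"]), istatic_th = unname(ist))
}

#' @export
print.compensation_result <- function(x, ...) {
  cat(sprintf("Compensation for %s: %.3g -> %.3g mS/cm2\n",
              x$perturbation$current, x$perturbation$reference_gbar,
              x$perturbation$new_gbar))
  print(round(x$x, 4))
  cat(sprintf("  max |residual| (frozen Ca): %.3g; (full): %.3g\n",
              max(abs(x$residuals)), max(abs(x$residuals_full))))
  cat(sprintf("  condition number: %.3g%s\n", x$condition,
              if (x$nonphysiological) "  [NONPHYSIOLOGICAL: negative conductance]"
              else ""))
  invisible(x)
}

#' Compensation along a path of perturbed densities
#'
#' Solves the compensation problem for a sequence of perturbed densities.
#' Because the preserved quantities are linear in the maximal conductances,
#' every component of the solution is an affine function of the perturbed
#' density (which can be verified on the output).
#'
#' @param model The reference [neuron_model()].
#' @param perturbed Perturbed calcium current name.
#' @param gbar_values Densities to compensate at.
#' @param targets Optional [make_targets()] result.
#' @param ... Passed to [compensate()].
#' @return Data frame with one row per density: the perturbed value, the
#'   solution components, `max_residual` and the nonphysiological flag. The
#'   full results are attached as attribute `results`.
#' @export
compensation_path <- function(model, perturbed, gbar_values, targets = NULL,
                              ...) {
  if (is.null(targets)) targets <- make_targets(model)
  res <- lapply(gbar_values, function(g)
    compensate(model, perturbed, g, targets, ...))
  df <- do.call(rbind, lapply(res, function(r)
    data.frame(gbar = r$perturbation$new_gbar, t(r$x),
               max_residual = max(abs(r$residuals)),
               nonphysiological = r$nonphysiological)))
  attr(df, "results") <- res
  df
}
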