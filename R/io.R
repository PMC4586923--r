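## ---- declarative model construction -------------------------------------

gate_from_list <- function(spec, role, where) {
  for (slot in c("inf", "tau"))
    if (is.null(spec[[slot]]) || is.null(spec[[slot]]$form) ||
        is.null(spec[[slot]]$params))
      stop("model config: ", where, ": ", role,
           " gate needs '", slot, ": {form, params}'")
  inf <- kinetics_fn(spec$inf$form, spec$inf$params)
  tau <- kinetics_fn(spec$tau$form, spec$tau$params)
  dic_gate(name = if (role == "activation") "m" else "h",
           role = role,
           exponent = if (is.null(spec$exponent)) 1L else spec$exponent,
           inf = inf, tau = tau,
           ca_dependent = identical(spec$inf$form, "ca_boltzmann"))
}

current_from_list <- function(spec) {
  for (fld in c("name", "gbar", "erev"))
    if (is.null(spec[[fld]]))
      stop("model config: current block missing field '", fld, "'")
  ionic_current(
    name = spec$name, gbar = spec$gbar, erev = spec$erev,
    activation = if (!is.null(spec$activation))
      gate_from_list(spec$activation, "activation", spec$name),
    inactivation = if (!is.null(spec$inactivation))
      gate_from_list(spec$inactivation, "inactivation", spec$name),
    calcium_carrying = isTRUE(spec$calcium_carrying),
    polarity = spec$polarity)
}

## Build a neuron_model from a declarative list (parsed config file).
model_from_list <- function(spec) {
  if (is.null(spec$currents) || length(spec$currents) == 0)
    stop("model config: no 'currents' block")
  currents <- lapply(spec$currents, current_from_list)
  desig <- spec$designation
  if (!is.null(desig)) desig <- as.list(desig)
  neuron_model(
    currents = currents,
    leak = if (is.null(spec$leak)) list(g = 0, erev = -50)
           else list(g = spec$leak$g, erev = spec$leak$erev),
    capacitance = if (is.null(spec$capacitance)) 1 else spec$capacitance,
    calcium = if (!is.null(spec$calcium))
      calcium_pool(tau = spec$calcium$tau, f = spec$calcium$f,
                   ca0 = spec$calcium$ca0),
    i_app = if (is.null(spec$i_app)) 0 else spec$i_app,
    v_range = if (is.null(spec$v_range)) c(-80, 50)
              else as.numeric(spec$v_range),
    designation = desig)
}

## Serialize a model whose gates carry registry metadata back to a list.
model_to_list <- function(model) {
  gate_to_list <- function(gate) {
    inf_form <- attr(gate$inf, "form")
    tau_form <- attr(gate$tau, "form")
    if (is.null(inf_form) || is.null(tau_form))
      stop("model is not serializable: gate '", gate$name,
           "' does not come from the kinetics registry")
    list(exponent = gate$exponent,
         inf = list(form = inf_form, params = attr(gate$inf, "params")),
         tau = list(form = tau_form, params = attr(gate$tau, "params")))
  }
  list(
    capacitance = model$capacitance,
    i_app = model$i_app,
    v_range = as.numeric(model$v_range),
    leak = model$leak,
    calcium = if (!is.null(model$calcium))
      list(tau = model$calcium$tau, f = model$calcium$f,
           ca0 = model$calcium$ca0),
    designation = model$designation,
    currents = unname(lapply(model$currents, function(cur) {
      out <- list(name = cur$name, gbar = cur$gbar, erev = cur$erev,
                  calcium_carrying = cur$calcium_carrying,
                  polarity = cur$polarity)
      if (!is.null(cur$activation))
        out$activation <- gate_to_list(cur$activation)
      if (!is.null(cur$inactivation))
        out$inactivation <- gate_to_list(cur$inactivation)
      out
    })))
}

#' Read a declarative model description
#'
#' Parses a YAML model configuration: either a bundled fixture with
#' overrides (`fixture: stg`, optional `overrides: {gbar: {...}, i_app: }`),
#' or a fully declarative model with per-current gating blocks naming
#' functional forms from the kinetics registry (see [kinetics_fn()]).
#'
#' @param path Path to a YAML file.
#' @return A [neuron_model()].
#' @export
read_model_config <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$fixture)) {
    ov <- spec$overrides
    return(make_fixture(spec$fixture,
                        gbar = unlist(ov$gbar),
                        i_app = ov$i_app))
  }
  model_from_list(spec)
}

#' Write a model as a declarative configuration file
#'
#' Only models whose gates carry kinetics-registry metadata (fixture or
#' config-built models) are serializable; round-trips through
#' [read_model_config()].
#'
#' @param model A [neuron_model()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  yaml::write_yaml(model_to_list(model), path)
  invisible(path)
}

## ---- analysis driver ----------------------------------------------------

write_csv_units <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run a configured set of analyses
#'
#' Drives the full pipeline over a model: timescale decomposition, clamp
#' measurement, markers, sensitivities, compensation and/or simulation, and
#' writes each result as a CSV with explicit units plus a `summary.yaml`
#' with the effective configuration (provenance). Independent analyses
#' continue when one fails; failures are reported per analysis.
#'
#' @param config Path to a YAML run configuration, or an equivalent list:
#'   fields `model` (fixture name, or a path to a model config),
#'   `analyses` (subset of `dic`, `clamp`, `markers`, `sensitivity`,
#'   `compensate`, `simulate`), and optional blocks `grid`
#'   (`from`, `to`, `by` in mV), `clamp` (`v_holds`, `delta_v`,
#'   `step_duration`), `compensate` (`perturbed`, `gbar_values`),
#'   `simulate` (`duration`, `dt_out`).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list of analysis results; errors are stored as
#'   `try-error` entries and reported in the summary.
#' @export
run_analysis <- function(config, outdir = ".") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$model)) stop("run config: missing 'model'")
  if (is.null(cfg$analyses)) stop("run config: missing 'analyses'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  model <- if (file.exists(cfg$model)) read_model_config(cfg$model)
           else make_fixture(cfg$model,
                             gbar = unlist(cfg$overrides$gbar),
                             i_app = cfg$overrides$i_app)
  grid <- if (!is.null(cfg$grid))
    seq(cfg$grid$from, cfg$grid$to, by = cfg$grid$by)
  else seq(model$v_range[1], model$v_range[2], by = 0.1)
  results <- list()
  for (an in cfg$analyses) {
    message("analysis: ", an)
    results[[an]] <- tryCatch(switch(an,
      dic = {
        d <- dic_curves(model, grid)
        write_csv_units(as.data.frame(d), file.path(outdir, "dic.csv"),
                        "v: mV; conductances: mS/cm2")
        d
      },
      markers = {
        mk <- voltage_markers(model)
        yaml::write_yaml(list(v_th = mk$v_th, v_osc = mk$v_osc,
                              vary = mk$meta$vary,
                              alpha_critical = mk$meta$alpha_critical),
                         file.path(outdir, "markers.yaml"))
        mk
      },
      sensitivity = {
        st <- sensitivity_table(model, grid)
        write_csv_units(st, file.path(outdir, "sensitivity.csv"),
                        "v: mV; f,s,u: (mS/cm2 per mS/cm2)")
        st
      },
      clamp = {
        pr <- if (!is.null(cfg$clamp))
          clamp_protocol(v_holds = as.numeric(cfg$clamp$v_holds),
                         delta_v = cfg$clamp$delta_v %||% 1,
                         step_duration = cfg$clamp$step_duration %||% 5000)
        else clamp_protocol(seq(model$v_range[1] + 5, -30, by = 5))
        md <- measure_dics(model, pr)
        write_csv_units(md, file.path(outdir, "clamp_dics.csv"),
                        "v: mV; conductances: mS/cm2")
        md
      },
      compensate = {
        if (is.null(cfg$compensate))
          stop("run config: 'compensate' block required")
        path <- compensation_path(model, cfg$compensate$perturbed,
                                  as.numeric(cfg$compensate$gbar_values))
        write_csv_units(path, file.path(outdir, "compensation.csv"),
                        "gbar, conductances: mS/cm2; i_app: uA/cm2")
        path
      },
      simulate = {
        dur <- cfg$simulate$duration %||% 5000
        tr <- simulate_model(model, dur,
                             dt_out = cfg$simulate$dt_out %||% 0.1)
        write_csv_units(tr, file.path(outdir, "trace.csv"),
                        "time: ms; v: mV; i_total: uA/cm2; gates: 1; Ca: uM")
        tr
      },
      stop("unknown analysis: '", an, "'")
    ), error = function(e) {
      message("analysis '", an, "' failed: ", conditionMessage(e))
      structure(conditionMessage(e), class = "try-error")
    })
  }
  failed <- names(results)[vapply(results, inherits, logical(1), "try-error")]
  yaml::write_yaml(list(
    package = "dicurves",
    version = as.character(utils::packageVersion("dicurves")),
    config = cfg,
    failed_analyses = as.list(failed)),
    file.path(outdir, "summary.yaml"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
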