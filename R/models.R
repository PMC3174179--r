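## Published model constants. Rate constants are per second (concentrations
## molar); time-course I/O elsewhere is in minutes.

## Cell-free (in vitro) rate constants. k2 is tied to k1 by construction.
.INVITRO_PARAMS <- c(
  k1 = 1.2e4,   # CPR_red + Dox_q, M-1 s-1 (fitted)
  k2 = 1.2e4,   # CPR_ox + NADPH, = k1
  k3 = 3.0e8,   # O2 + Dox_sq re-oxidation, M-1 s-1
  k4 = 2.9e1,   # non-enzymatic NADPH + O2, M-1 s-1 (fitted)
  k5 = 5.5e7,   # O2- + Dox_q, M-1 s-1 (fitted)
  k6 = 6.4e9,   # spontaneous dismutation, M-1 s-1
  k_sod = 2e9,  # SOD-catalyzed dismutation, M-1 s-1 (diffusion-limited order)
  sod_conc = 0  # SOD enzyme concentration, M (0 = absent)
)

.INVITRO_STATE <- c(CPR_red = 1.0e-6, CPR_ox = 0, Dox_q = 1.0e-4, Dox_sq = 0,
                    NADPH = 1.0e-4, NADP = 0, O2 = 2.7e-4, O2minus = 0,
                    H2O2 = 0)

## Cell-based (in vivo) constants for the doxorubicin-resistant line (EU1-Res);
## the sensitive line (EU3-Sens) is derived by measured fold changes.
.INVIVO_PARAMS <- c(
  k1 = 1.2e4,    # from the cell-free model
  k2 = 1.2e4,    # = k1
  k3 = 3.0e5,    # intracellular semiquinone re-oxidation, M-1 s-1
  k4 = 4.2e4,    # NOX4-dependent NADPH + O2, M-1 s-1
  k5 = 5.5e7,
  k6 = 6.4e9,    # SOD1-dependent dismutation
  k7 = 1.1e-6,   # membrane permeability, cm s-1 (10 uM condition; fitted)
  A  = 6.15,     # aggregate surface factor, cm-1:
                 # 1e-3 L cm-3 * 6.15e-6 cm2/cell * 1e9 cells/L
  k8 = 1.8e-6,   # G6PD NADPH supply Vmax, M s-1 (fitted)
  k9 = 5.7e-5,   # G6PD half-saturation in NADP, M
  k_dox = 1e-7,  # half-saturation of the NOX4 drug dependence, M
  vol_ratio = 1e4  # medium-to-cytosol volume ratio (1 / cytosolic fraction)
)

.INVIVO_STATE_EU1 <- c(CPR_red = 1.3e-6, CPR_ox = 0, Ex_Dox_q = 1.0e-5,
                       In_Dox_q = 0, In_Dox_sq = 0, NADPH = 3.0e-5,
                       NADP = 0.01 * 3.0e-5, O2 = 1.5e-9, O2minus = 1.5e-11,
                       H2O2 = 1.5e-11)

.INVIVO_K7 <- c(high = 1.1e-6, low = 1.1e-5)  # 10 uM vs 100 nM condition

#' Measured fold changes between the resistant and sensitive ALL lines
#'
#' Multipliers applied to the EU1-Res (resistant) reference to obtain the
#' EU3-Sens (sensitive) model: reduced-CPR concentration, basal NADPH, the
#' NOX4-linked constant `k4`, the G6PD-linked supply `k8`, and the
#' SOD1-linked constant `k6` (no measured difference, so 1). The resistant
#' profile is all ones.
#'
#' @param cell_line `"EU1-Res"` or `"EU3-Sens"`.
#' @return named numeric vector of multipliers.
#' @export
cell_line_profile <- function(cell_line = c("EU1-Res", "EU3-Sens")) {
  cell_line <- match.arg(cell_line)
  if (cell_line == "EU1-Res")
    return(c(CPR_red = 1, NADPH = 1, k4 = 1, k8 = 1, k6 = 1))
  c(CPR_red = 8.9e-7 / 1.3e-6,  # measured reduced CPR
    NADPH   = 5.4e-5 / 3.0e-5,  # measured basal NADPH
    k4      = 9.7e3 / 4.2e4,    # NOX4-linked
    k8      = 3.3e-6 / 1.8e-6,  # G6PD-linked
    k6      = 1)                # SOD1: no significant difference
}

#' Scenario configuration for a bioactivation model
#'
#' Declares which published model variant to build and under which
#' experimental condition. The defaults are the study conditions: the
#' cell-free model at 100 uM NADPH without SOD, or a cell model at the
#' 10 uM extracellular doxorubicin dose.
#'
#' @param kind `"in_vitro"` (cell-free reaction mixture) or `"in_vivo"`
#'   (whole-cell model).
#' @param nadph0 initial NADPH for the cell-free model, M (the published
#'   conditions are `1e-4` and `5e-4`).
#' @param sod logical; include the SOD-catalyzed dismutation term
#'   (cell-free model only).
#' @param sod_conc SOD enzyme concentration when `sod = TRUE`, M.
#' @param cell_line `"EU1-Res"` or `"EU3-Sens"` (cell model only).
#' @param dose extracellular doxorubicin, M; `1e-5` and `1e-7` are the
#'   published conditions and select the dose-specific permeability `k7`.
#' @param interventions list of `list(target=, fraction=)` entries applied
#'   with [apply_intervention()]; the name `"DHEA"` is an alias for `k8`.
#' @param oxygen_clamp logical; hold intracellular O2 at its initial value
#'   (continuous re-supply from the medium). Default `TRUE` for the cell
#'   model, ignored for the cell-free model.
#' @param r4_mode `"dox_modulated"` (NOX4 activity saturably dependent on
#'   intracellular quinone drug) or `"table_literal"` (plain bimolecular
#'   form).
#' @param k_dox half-saturation of the drug modulation, M.
#' @param vol_ratio medium-to-cytosol volume ratio coupling drug uptake.
#' @param strict reject doses/NADPH values outside the published conditions
#'   unless `FALSE`.
#' @return an object of class `dox_scenario`.
#' @export
dox_scenario <- function(kind = c("in_vitro", "in_vivo"),
                         nadph0 = 1.0e-4, sod = FALSE, sod_conc = 1e-6,
                         cell_line = c("EU1-Res", "EU3-Sens"), dose = 1.0e-5,
                         interventions = list(), oxygen_clamp = TRUE,
                         r4_mode = c("dox_modulated", "table_literal"),
                         k_dox = 1e-7, vol_ratio = 1e4, strict = TRUE) {
  kind <- match.arg(kind)
  cell_line <- match.arg(cell_line)
  r4_mode <- match.arg(r4_mode)
  if (strict) {
    if (kind == "in_vitro" && !nadph0 %in% c(1.0e-4, 5.0e-4))
      stop("nadph0 must be 1e-4 or 5e-4 M (use strict = FALSE to override)")
    if (kind == "in_vivo" && !dose %in% c(1.0e-5, 1.0e-7))
      stop("dose must be 1e-5 or 1e-7 M (use strict = FALSE to override)")
  }
  for (iv in interventions)
    if (!is.list(iv) || is.null(iv$target) || is.null(iv$fraction))
      stop("each intervention must be list(target=, fraction=)")
  structure(list(kind = kind, nadph0 = nadph0, sod = sod,
                 sod_conc = sod_conc, cell_line = cell_line, dose = dose,
                 interventions = interventions, oxygen_clamp = oxygen_clamp,
                 r4_mode = r4_mode, k_dox = k_dox, vol_ratio = vol_ratio),
            class = "dox_scenario")
}

.invitro_reactions <- function(include_sod) {
  rx <- list(
    dox_reaction("R1", "bimolecular_mass_action", "k1",
                 reactants = c(CPR_red = 1, Dox_q = 1),
                 produces = c(CPR_ox = 1, Dox_sq = 1)),
    dox_reaction("R2", "bimolecular_mass_action", "k2",
                 reactants = c(CPR_ox = 1, NADPH = 1),
                 produces = c(CPR_red = 1, NADP = 1)),
    dox_reaction("R3", "bimolecular_mass_action", "k3",
                 reactants = c(O2 = 1, Dox_sq = 1),
                 produces = c(O2minus = 1, Dox_q = 1)),
    dox_reaction("R4", "bimolecular_mass_action", "k4",
                 reactants = c(NADPH = 1, O2 = 1),
                 produces = c(NADP = 1, O2minus = 1)),
    dox_reaction("R5", "bimolecular_mass_action", "k5",
                 reactants = c(O2minus = 1, Dox_q = 1),
                 produces = c(Dox_sq = 1, O2 = 1)),
    ## Spontaneous dismutation: 2 O2- consumed per event, peroxide formed;
    ## the oxygen is not returned to the O2 pool (terminal sink), in contrast
    ## to the SOD-catalyzed route below which regenerates O2 and thereby
    ## sustains semiquinone re-oxidation.
    dox_reaction("R6", "bimolecular_mass_action", "k6",
                 reactants = c(O2minus = 2),
                 consumes = c(O2minus = 2),
                 produces = c(H2O2 = 1)))
  if (include_sod)
    rx <- c(rx, list(
      dox_reaction("SOD", "bimolecular_mass_action", "k_sod",
                   reactants = c(O2minus = 1),
                   factor = "sod_conc",
                   produces = c(H2O2 = 0.5, O2 = 0.5))))
  rx
}

.invivo_reactions <- function(r4_mode, vol_ratio) {
  modulation <- if (r4_mode == "dox_modulated")
    list(species = "In_Dox_q", km = "k_dox") else NULL
  list(
    dox_reaction("R1", "bimolecular_mass_action", "k1",
                 reactants = c(CPR_red = 1, In_Dox_q = 1),
                 produces = c(CPR_ox = 1, In_Dox_sq = 1)),
    dox_reaction("R2", "bimolecular_mass_action", "k2",
                 reactants = c(CPR_ox = 1, NADPH = 1),
                 produces = c(CPR_red = 1, NADP = 1)),
    dox_reaction("R3", "bimolecular_mass_action", "k3",
                 reactants = c(O2 = 1, In_Dox_sq = 1),
                 produces = c(O2minus = 1, In_Dox_q = 1)),
    dox_reaction("R4", "bimolecular_mass_action", "k4",
                 reactants = c(NADPH = 1, O2 = 1),
                 produces = c(NADP = 1, O2minus = 1),
                 modulation = modulation),
    dox_reaction("R5", "bimolecular_mass_action", "k5",
                 reactants = c(O2minus = 1, In_Dox_q = 1),
                 produces = c(In_Dox_sq = 1, O2 = 1)),
    ## SOD1-catalyzed in the cell: O2 is regenerated.
    dox_reaction("R6", "bimolecular_mass_action", "k6",
                 reactants = c(O2minus = 2),
                 consumes = c(O2minus = 2),
                 produces = c(H2O2 = 1, O2 = 1)),
    ## Transport: the rate is the loss from the extracellular pool; uptake is
    ## concentrated into the cytosol by the volume ratio.
    dox_reaction("R7", "permeation", "k7",
                 reactants = c(Ex_Dox_q = 1), factor = "A",
                 consumes = c(Ex_Dox_q = 1),
                 produces = c(In_Dox_q = vol_ratio)),
    dox_reaction("R8", "saturable_supply", "k8", km = "k9",
                 reactants = c(NADP = 1),
                 consumes = c(NADP = 1),
                 produces = c(NADPH = 1)))
}

#' Build the cell-free (in vitro) bioactivation model
#'
#' Nine species (reduced/oxidized CPR, quinone and semiquinone doxorubicin,
#' NADPH/NADP, O2, superoxide, H2O2) and reactions R1-R6, with an optional
#' SOD-catalyzed dismutation term. Initial conditions are the published
#' reaction-mixture values; all product species start at zero.
#'
#' @param scenario a [dox_scenario()] with `kind = "in_vitro"`.
#' @return an object of class `dox_model`.
#' @export
build_invitro_model <- function(scenario = dox_scenario("in_vitro")) {
  stopifnot(inherits(scenario, "dox_scenario"))
  if (scenario$kind != "in_vitro")
    stop("scenario kind is not in_vitro")
  params <- .INVITRO_PARAMS
  if (scenario$sod) params[["sod_conc"]] <- scenario$sod_conc
  state0 <- .INVITRO_STATE
  state0[["NADPH"]] <- scenario$nadph0
  net <- dox_network(names(state0), .invitro_reactions(scenario$sod))
  model <- structure(list(network = net, params = params, state0 = state0,
                          clamp = NULL, scenario = scenario),
                     class = "dox_model")
  .apply_scenario_interventions(model)
}

#' Build a cell-line-specific (in vivo) bioactivation model
#'
#' Ten species and reactions R1-R8. The resistant-line (EU1-Res) constants
#' are used directly; the sensitive line (EU3-Sens) is derived by the
#' measured fold changes of [cell_line_profile()]. The dose selects the
#' condition-specific permeability `k7`, and initial NADP is 1 percent of
#' initial NADPH. Intracellular O2 is clamped at its initial value by
#' default (continuous supply from the medium).
#'
#' @param scenario a [dox_scenario()] with `kind = "in_vivo"`.
#' @return an object of class `dox_model`.
#' @export
build_invivo_model <- function(scenario = dox_scenario("in_vivo")) {
  stopifnot(inherits(scenario, "dox_scenario"))
  if (scenario$kind != "in_vivo")
    stop("scenario kind is not in_vivo")
  prof <- cell_line_profile(scenario$cell_line)
  params <- .INVIVO_PARAMS
  params[["k4"]] <- params[["k4"]] * prof[["k4"]]
  params[["k8"]] <- params[["k8"]] * prof[["k8"]]
  params[["k6"]] <- params[["k6"]] * prof[["k6"]]
  params[["k7"]] <- if (scenario$dose >= 1e-6) .INVIVO_K7[["high"]] else
    .INVIVO_K7[["low"]]
  params[["k_dox"]] <- scenario$k_dox
  params[["vol_ratio"]] <- scenario$vol_ratio
  state0 <- .INVIVO_STATE_EU1
  state0[["CPR_red"]] <- state0[["CPR_red"]] * prof[["CPR_red"]]
  state0[["NADPH"]] <- state0[["NADPH"]] * prof[["NADPH"]]
  state0[["NADP"]] <- 0.01 * state0[["NADPH"]]
  state0[["Ex_Dox_q"]] <- scenario$dose
  net <- dox_network(names(state0),
                     .invivo_reactions(scenario$r4_mode, scenario$vol_ratio))
  clamp <- if (isTRUE(scenario$oxygen_clamp)) c(O2 = state0[["O2"]]) else NULL
  model <- structure(list(network = net, params = params, state0 = state0,
                          clamp = clamp, scenario = scenario),
                     class = "dox_model")
  .apply_scenario_interventions(model)
}

.apply_scenario_interventions <- function(model) {
  for (iv in model$scenario$interventions)
    model <- apply_intervention(model, iv$target, iv$fraction)
  model
}

#' Build a model from a scenario
#'
#' Dispatches to [build_invitro_model()] or [build_invivo_model()].
#'
#' @param scenario a [dox_scenario()].
#' @return a `dox_model`.
#' @export
dox_model <- function(scenario = dox_scenario()) {
  if (scenario$kind == "in_vitro") build_invitro_model(scenario)
  else build_invivo_model(scenario)
}

#' Apply a fractional enzyme inhibition in silico
#'
#' Returns a copy of the model with the target rate constant scaled by
#' `1 - fraction`; the input model is untouched. `"DHEA"` (the
#' pharmacological G6PD inhibitor) is an alias for `k8`.
#'
#' @param model a `dox_model`.
#' @param target parameter name, or `"DHEA"`.
#' @param fraction inhibited fraction in `[0, 1]`; the published
#'   intervention simulations assume 0.2.
#' @return the modified `dox_model`.
#' @export
apply_intervention <- function(model, target, fraction = 0.2) {
  if (identical(target, "DHEA")) target <- "k8"
  if (!target %in% names(model$params))
    stop("unknown intervention target: ", target)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("inhibition fraction must be in [0, 1]")
  model$params[[target]] <- model$params[[target]] * (1 - fraction)
  model
}

#' Set a model parameter, preserving tied constants
#'
#' `k2` is defined equal to `k1`; setting `k1` updates both.
#'
#' @param model a `dox_model`.
#' @param name parameter name.
#' @param value new value (> 0).
#' @return the modified `dox_model`.
#' @export
set_param <- function(model, name, value) {
  if (!name %in% names(model$params))
    stop("unknown parameter: ", name)
  model$params[[name]] <- value
  if (name == "k1") model$params[["k2"]] <- value
  model
}

#' @export
coef.dox_model <- function(object, ...) object$params

#' @export
print.dox_model <- function(x, ...) {
  sc <- x$scenario
  if (sc$kind == "in_vitro") {
    cat(sprintf("Cell-free doxorubicin bioactivation model (%d species)\n",
                length(x$network$species)))
    cat(sprintf("  [NADPH]0 = %g M, SOD %s\n", sc$nadph0,
                if (sc$sod) sprintf("present (%g M)", sc$sod_conc) else
                  "absent"))
  } else {
    cat(sprintf("Cell model of doxorubicin bioactivation (%d species)\n",
                length(x$network$species)))
    cat(sprintf("  cell line %s, dose %g M, O2 %s\n", sc$cell_line, sc$dose,
                if (length(x$clamp)) "clamped" else "dynamic"))
  }
  if (length(sc$interventions))
    for (iv in sc$interventions)
      cat(sprintf("  intervention: %s inhibited by %g%%\n", iv$target,
                  100 * iv$fraction))
  cat("  parameters:\n")
  print(x$params)
  invisible(x)
}

#' Serialize a scenario to a configuration file
#'
#' JSON (default) or YAML, chosen by file extension. Rebuilding a model from
#' the written configuration reproduces identical parameters and initial
#' state.
#'
#' @param scenario a [dox_scenario()].
#' @param path output file (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to write YAML configurations")
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a scenario configuration
#'
#' @param path a file written by [write_scenario()] (or hand-written in the
#'   same dialect).
#' @return a `dox_scenario`.
#' @export
read_scenario <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configurations")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(dox_scenario))
  bad <- setdiff(names(x), c(known, "strict"))
  if (length(bad))
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  if (!is.null(x$interventions)) {
    if (is.data.frame(x$interventions))
      x$interventions <- lapply(seq_len(nrow(x$interventions)), function(i)
        as.list(x$interventions[i, ]))
    x$interventions <- lapply(x$interventions, as.list)
  }
  do.call(dox_scenario, x)
}
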