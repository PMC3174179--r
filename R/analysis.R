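#' Classify the dominant drug-metabolism mode of a trajectory
#'
#' Reductive conversion shows net transformation of the quinone drug into
#' its semiquinone (with conservative NADPH depletion); redox cycling leaves
#' the quinone pool sustained (with rapid NADPH depletion) because every
#' semiquinone is re-oxidized by molecular oxygen. The classifier computes
#' the net fractional quinone transformation
#' `1 - q(end) / max(q)` and calls the mode `reductive_conversion` when it
#' exceeds `theta`.
#'
#' The threshold is a package convention: the published assignment is
#' qualitative, from curve shape. The statistic is invariant to uniform
#' rescaling of the concentration units.
#'
#' @param tc a species `dox_timecourse` containing the quinone series
#'   (`Dox_q` or `In_Dox_q`).
#' @param theta classification threshold on the transformed fraction.
#' @return `"reductive_conversion"` or `"redox_cycling"`, with the
#'   transformed fraction in attribute `"transformed_fraction"`.
#' @export
classify_metabolic_mode <- function(tc, theta = 0.2) {
  q_name <- intersect(c("Dox_q", "In_Dox_q"), names(tc$values))
  if (!length(q_name))
    stop("time course has no quinone doxorubicin series")
  q <- tc$values[[q_name[1]]]
  frac <- if (max(q) > 0) 1 - q[length(q)] / max(q) else 0
  mode <- if (frac > theta) "reductive_conversion" else "redox_cycling"
  structure(mode, transformed_fraction = frac)
}

.READOUTS <- c("quinone_accumulation", "nadph_depletion",
               "superoxide_production")

## End-of-window readouts used by the sensitivity scan: quinone level at
## t_end, depleted NADPH fraction at t_end, cumulative superoxide production
## (M) over [0, t_end].
.model_readouts <- function(model, t_end = 60, dense_dt = 0.1) {
  grid <- seq(0, t_end, by = dense_dt)
  tc <- simulate_timecourse(model, grid)
  q_sp <- if (model$scenario$kind == "in_vitro") "Dox_q" else "In_Dox_q"
  rt <- rates_timecourse(model, tc)
  prod_rate <- (rt$values[["R3"]] %||% 0) + (rt$values[["R4"]] %||% 0)
  c(quinone_accumulation = tc$values[[q_sp]][length(grid)],
    nadph_depletion = 1 - tc$values[["NADPH"]][length(grid)] /
      tc$values[["NADPH"]][1],
    superoxide_production = .trapz(grid * 60, prod_rate))
}

.perturb_quantity <- function(model, quantity, factor) {
  if (quantity %in% names(model$params))
    return(set_param(model, quantity, model$params[[quantity]] * factor))
  if (quantity %in% names(model$state0)) {
    model$state0[[quantity]] <- model$state0[[quantity]] * factor
    if (quantity == "NADPH")  # basal NADP is tied to basal NADPH
      model$state0[["NADP"]] <- 0.01 * model$state0[["NADPH"]]
    if (length(model$clamp) && quantity %in% names(model$clamp))
      model$clamp[[quantity]] <- model$clamp[[quantity]] * factor
    return(model)
  }
  stop("unknown quantity: ", quantity)
}

#' Local sensitivity scan of model readouts
#'
#' Each quantity (a rate constant or an initial concentration) is perturbed
#' one at a time by `±delta` and the normalized sensitivity coefficient of
#' each 60-minute readout is computed by central difference:
#' `S = (O(x(1+delta)) - O(x(1-delta))) / O(x) / (2 delta)`.
#' Readouts are quinone accumulation, NADPH depletion and cumulative
#' superoxide production. Coefficients are flagged undefined (NA) when the
#' baseline readout is numerically zero.
#'
#' The default quantity set targets the enzymatic controls of the cell
#' model: the G6PD supply `k8`, the SOD constant `k6`, the NOX constant
#' `k4`, and the initial NADPH, reduced-CPR and O2 concentrations; the
#' default model is the resistant line at the 10 uM dose.
#'
#' @param model a `dox_model`.
#' @param quantities character vector of parameter and/or species names.
#' @param delta relative perturbation.
#' @param t_end readout horizon, minutes.
#' @param dense_dt integration grid step for the cumulative readout.
#' @return a data frame of class `dox_sensitivity` with one row per
#'   quantity x readout.
#' @export
sensitivity_scan <- function(model = build_invivo_model(),
                             quantities = c("k8", "k6", "k4", "NADPH",
                                            "CPR_red", "O2"),
                             delta = 0.10, t_end = 60, dense_dt = 0.1) {
  base <- .model_readouts(model, t_end, dense_dt)
  rows <- list()
  for (q in quantities) {
    up <- .model_readouts(.perturb_quantity(model, q, 1 + delta),
                          t_end, dense_dt)
    dn <- .model_readouts(.perturb_quantity(model, q, 1 - delta),
                          t_end, dense_dt)
    s <- ifelse(abs(base) > 0, (up - dn) / base / (2 * delta), NA_real_)
    rows[[q]] <- data.frame(quantity = q, readout = .READOUTS,
                            baseline = unname(base), S = unname(s))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dox_sensitivity", "data.frame")
  attr(out, "delta") <- delta
  out
}

#' @export
print.dox_sensitivity <- function(x, ...) {
  cat(sprintf("Normalized sensitivity coefficients (central difference, delta = %g)\n",
              attr(x, "delta")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Compare semiquinone and superoxide fluxes under an intervention
#'
#' For each cell line x dose condition, integrates the
#' semiquinone-formation flux (R1) and the NADPH-dependent superoxide flux
#' (R4) over the treatment window with and without a fractional inhibition
#' of the target (default: 20 percent G6PD inhibition, the DHEA
#' simulation), and reports the intervention/control ratios.
#'
#' @param cell_lines,doses the scenario grid (defaults: both lines at both
#'   published doses).
#' @param target,fraction the intervention (see [apply_intervention()]).
#' @param window integration window, minutes.
#' @param dense_dt trajectory grid step for the flux integrals, minutes.
#' @param scenario_args extra arguments passed to [dox_scenario()].
#' @return a data frame of class `dox_flux_comparison` with control and
#'   intervention integrals (M) and their ratios.
#' @export
compare_intervention_fluxes <- function(cell_lines = c("EU1-Res", "EU3-Sens"),
                                        doses = c(1e-5, 1e-7),
                                        target = "DHEA", fraction = 0.2,
                                        window = c(0, 60), dense_dt = 0.1,
                                        scenario_args = list()) {
  grid <- seq(window[1], window[2], by = dense_dt)
  rows <- list()
  for (dose in doses) for (cl in cell_lines) {
    sc <- do.call(dox_scenario,
                  c(list(kind = "in_vivo", cell_line = cl, dose = dose),
                    scenario_args))
    ctrl <- build_invivo_model(sc)
    trt <- apply_intervention(ctrl, target, fraction)
    fl <- function(m) {
      tc <- simulate_timecourse(m, grid)
      c(R1 = integrated_flux(m, tc, "R1", window),
        R4 = integrated_flux(m, tc, "R4", window))
    }
    f0 <- fl(ctrl); f1 <- fl(trt)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_line = cl, dose = dose, target = target, fraction = fraction,
      semiquinone_control = f0[["R1"]], semiquinone_intervention = f1[["R1"]],
      semiquinone_ratio = if (f0[["R1"]] > 0) f1[["R1"]] / f0[["R1"]] else NA,
      superoxide_control = f0[["R4"]], superoxide_intervention = f1[["R4"]],
      superoxide_ratio = if (f0[["R4"]] > 0) f1[["R4"]] / f0[["R4"]] else NA)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dox_flux_comparison", "data.frame")
  out
}

#' @export
print.dox_flux_comparison <- function(x, ...) {
  cat("Time-integrated fluxes, intervention vs control\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
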