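#' Time-course container
#'
#' A thin container for trajectories on a common time grid: a strictly
#' increasing grid in minutes plus one or more named series with units and
#' normalization metadata.
#'
#' @param time_min numeric grid, minutes, strictly increasing.
#' @param values data frame (or matrix) of series, one column per series,
#'   `length(time_min)` rows.
#' @param kind one of `"species"`, `"observable"`, `"flux"` per series
#'   (recycled).
#' @param units character, per series (recycled).
#' @param normalization `"raw"`, `"max"` or `"fraction_of_basal"` per series
#'   (recycled).
#' @return an object of class `dox_timecourse`.
#' @export
dox_timecourse <- function(time_min, values, kind = "species", units = "M",
                           normalization = "raw") {
  values <- as.data.frame(values)
  if (length(time_min) != nrow(values))
    stop("series length does not match the time grid")
  if (length(time_min) > 1 && any(diff(time_min) <= 0))
    stop("time grid must be strictly increasing")
  n <- ncol(values)
  structure(list(time_min = as.numeric(time_min), values = values,
                 kind = rep_len(kind, n), units = rep_len(units, n),
                 normalization = rep_len(normalization, n)),
            class = "dox_timecourse")
}

#' @export
print.dox_timecourse <- function(x, ...) {
  cat(sprintf("Time course: %d points, %.6g-%.6g min; %d series\n",
              length(x$time_min), min(x$time_min), max(x$time_min),
              ncol(x$values)))
  for (i in seq_along(x$values))
    cat(sprintf("  %-18s %-10s %-4s %s\n", names(x$values)[i], x$kind[i],
                x$units[i], x$normalization[i]))
  invisible(x)
}

#' @export
as.data.frame.dox_timecourse <- function(x, ...) {
  if (!ncol(x$values))
    return(data.frame(time_min = numeric(0), series = character(0),
                      value = numeric(0), units = character(0),
                      normalization = character(0)))
  long <- do.call(rbind, lapply(seq_along(x$values), function(i)
    data.frame(time_min = x$time_min, series = names(x$values)[i],
               value = x$values[[i]], units = x$units[i],
               normalization = x$normalization[i])))
  long[order(long$series, long$time_min), , drop = FALSE]
}

#' @export
plot.dox_timecourse <- function(x, series = names(x$values), log = "", ...) {
  m <- as.matrix(x$values[series])
  graphics::matplot(x$time_min, m, type = "l", lty = 1,
                    xlab = "time (min)", ylab = "value", log = log, ...)
  graphics::legend("topright", legend = series, lty = 1,
                   col = seq_along(series), bty = "n", cex = 0.8)
  invisible(x)
}

## deSolve interface: time in seconds internally; the RHS is the compiled
## fast path of .compile_model().

#' Integrate a model over a time grid
#'
#' Stiff-capable integration (deSolve's `lsoda`) of the mass-action network,
#' reported exactly at the requested grid points. Rate constants are per
#' second; the grid is in minutes.
#'
#' @param model a `dox_model`.
#' @param t_grid time grid, minutes (must start at 0 or the integration
#'   starts from the model's initial state at the first point).
#' @param rtol,atol integrator tolerances. The defaults resolve species
#'   spanning roughly 1e-11 to 1e-3 M.
#' @return a `dox_timecourse` of species concentrations.
#' @export
simulate_timecourse <- function(model, t_grid = seq(0, 60, by = 1),
                                rtol = 1e-8, atol = 1e-14) {
  stopifnot(inherits(model, "dox_model"))
  t_sec <- t_grid * 60
  prepend0 <- t_sec[1] > 0
  if (prepend0) t_sec <- c(0, t_sec)
  rhs <- .compile_model(model)
  out <- deSolve::lsoda(model$state0, t_sec, rhs, NULL,
                        rtol = rtol, atol = atol, maxsteps = 20000)
  if (!is.matrix(out) || nrow(out) < length(t_sec)) {
    last_t <- if (is.matrix(out)) max(out[, "time"]) / 60 else NA_real_
    stop(sprintf("integration failed; last good time %.4g min", last_t))
  }
  vals <- as.data.frame(out[, model$network$species, drop = FALSE])
  if (prepend0) vals <- vals[-1, , drop = FALSE]
  rownames(vals) <- NULL
  dox_timecourse(t_grid, vals)
}

#' Reaction rates along a trajectory
#'
#' @param model the `dox_model` that produced `tc`.
#' @param tc a species `dox_timecourse`.
#' @return a `dox_timecourse` of per-reaction rates (M/s), kind `"flux"`.
#' @export
rates_timecourse <- function(model, tc) {
  states <- as.matrix(tc$values)
  r <- apply(states, 1, function(s) evaluate_rates(model, s))
  r <- if (is.matrix(r)) t(r) else
    matrix(r, ncol = 1,
           dimnames = list(NULL, names(model$network$reactions)))
  dox_timecourse(tc$time_min, as.data.frame(r), kind = "flux",
                 units = "M/s")
}

.trapz <- function(t, v) {
  if (length(t) < 2) return(0)
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Time-integrated reaction flux
#'
#' Trapezoidal integral of a reaction rate along the trajectory over a time
#' window (default the full trajectory). The semiquinone-formation flux is
#' the R1 integral; the NADPH-dependent superoxide flux is the R4 integral.
#'
#' @param model the `dox_model` that produced `tc`.
#' @param tc a species `dox_timecourse` (use a reasonably dense grid; the
#'   integral is exact only in the trapezoid sense on that grid).
#' @param reaction reaction id, e.g. `"R1"`.
#' @param window `c(from, to)` in minutes; must lie on the grid range.
#' @return non-negative scalar, molar.
#' @export
integrated_flux <- function(model, tc, reaction,
                            window = range(tc$time_min)) {
  if (!reaction %in% names(model$network$reactions))
    stop("unknown reaction: ", reaction)
  if (window[1] < min(tc$time_min) - 1e-9 ||
      window[2] > max(tc$time_min) + 1e-9)
    stop("window outside the trajectory grid")
  keep <- tc$time_min >= window[1] - 1e-9 & tc$time_min <= window[2] + 1e-9
  states <- as.matrix(tc$values)[keep, , drop = FALSE]
  rate <- apply(states, 1, function(s)
    evaluate_rates(model, s)[[reaction]])
  .trapz(tc$time_min[keep] * 60, rate)
}

.OBSERVABLES <- c("quinone_dox", "nadph", "superoxide_signal",
                  "extracellular_dox", "semiquinone_dox")

#' Map a simulated trajectory to experimental observables
#'
#' Observables mirror the assay readouts: `quinone_dox` is the
#' (intracellular) quinone drug concentration; `nadph` the NADPH fraction of
#' basal; `superoxide_signal` the cumulative superoxide production integral
#' of R3 + R4 (an irreversibly oxidized probe accumulates signal), normalized
#' to its end-of-window maximum; `extracellular_dox` the extracellular
#' quinone pool; `semiquinone_dox` the (intracellular) semiquinone pool.
#'
#' The cumulative integral is computed on an internally refined grid
#' (`dense_dt` minutes) and sampled at the requested points.
#'
#' @param model a `dox_model`.
#' @param t_grid reporting grid, minutes.
#' @param observables subset of the supported observable ids.
#' @param dense_dt internal refinement step for cumulative integrals,
#'   minutes.
#' @param rtol,atol integrator tolerances.
#' @return a `dox_timecourse` of observables.
#' @export
compute_observables <- function(model, t_grid = seq(0, 60, by = 10),
                                observables = NULL, dense_dt = 0.1,
                                rtol = 1e-8, atol = 1e-14) {
  vitro <- model$scenario$kind == "in_vitro"
  if (is.null(observables))
    observables <- if (vitro) c("quinone_dox", "nadph") else
      c("quinone_dox", "nadph", "superoxide_signal", "extracellular_dox")
  bad <- setdiff(observables, .OBSERVABLES)
  if (length(bad)) stop("unknown observable(s): ", paste(bad, collapse = ", "))
  q_sp <- if (vitro) "Dox_q" else "In_Dox_q"
  sq_sp <- if (vitro) "Dox_sq" else "In_Dox_sq"
  need_dense <- "superoxide_signal" %in% observables
  grid <- if (need_dense)
    sort(unique(c(t_grid, seq(min(t_grid), max(t_grid), by = dense_dt))))
  else t_grid
  tc <- simulate_timecourse(model, grid, rtol = rtol, atol = atol)
  at <- match(t_grid, grid)
  vals <- list(); units <- c(); norm <- c()
  for (ob in observables) {
    v <- switch(ob,
      quinone_dox = list(tc$values[[q_sp]][at], "M", "raw"),
      semiquinone_dox = list(tc$values[[sq_sp]][at], "M", "raw"),
      extracellular_dox = list(tc$values[["Ex_Dox_q"]][at], "M", "raw"),
      nadph = list(tc$values[["NADPH"]][at] / tc$values[["NADPH"]][1],
                   "fraction", "fraction_of_basal"),
      superoxide_signal = {
        rt <- rates_timecourse(model, tc)
        prod_rate <- rt$values[["R3"]] + rt$values[["R4"]]
        cum <- c(0, cumsum(diff(grid * 60) *
                           (utils::head(prod_rate, -1) +
                            utils::tail(prod_rate, -1)) / 2))
        mx <- max(cum)
        list(if (mx > 0) cum[at] / mx else cum[at], "fraction", "max")
      })
    vals[[ob]] <- v[[1]]; units <- c(units, v[[2]]); norm <- c(norm, v[[3]])
  }
  dox_timecourse(t_grid, as.data.frame(vals), kind = "observable",
                 units = units, normalization = norm)
}

#' Predicted trajectories from a model
#'
#' `predict` returns observables (default) or raw species concentrations on
#' a time grid.
#'
#' @param object a `dox_model`.
#' @param t_grid reporting grid, minutes.
#' @param type `"observables"` or `"species"`.
#' @param ... passed to [compute_observables()] / [simulate_timecourse()].
#' @return a `dox_timecourse`.
#' @export
predict.dox_model <- function(object, t_grid = seq(0, 60, by = 10),
                              type = c("observables", "species"), ...) {
  type <- match.arg(type)
  if (type == "species") simulate_timecourse(object, t_grid, ...)
  else compute_observables(object, t_grid, ...)
}
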