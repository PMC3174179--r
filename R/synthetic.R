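#' Noise model for pseudo-experimental data
#'
#' Additive Gaussian noise with standard deviation expressed as a fraction
#' of each series' maximum (assay-level noise on normalized plate-reader
#' series), applied independently to each of `replicates` biological
#' replicates. The same seed always reproduces the same dataset.
#'
#' @param sigma noise standard deviation as a fraction of the series max.
#' @param replicates number of replicates.
#' @param seed integer RNG seed.
#' @return an object of class `dox_noise`.
#' @export
dox_noise <- function(sigma = 0.02, replicates = 3, seed = 1L) {
  stopifnot(sigma >= 0, replicates >= 1)
  structure(list(sigma = sigma, replicates = as.integer(replicates),
                 seed = as.integer(seed)), class = "dox_noise")
}

.synth_dataset <- function(scenario, t_grid, clean, noise, clip_upper) {
  set.seed(noise$seed)
  reps <- list()
  clipped <- 0L
  for (j in names(clean)) {
    base <- clean[[j]]
    sd_j <- noise$sigma * max(base)
    m <- matrix(stats::rnorm(length(base) * noise$replicates,
                             mean = base, sd = sd_j),
                nrow = length(base))
    clipped <- clipped + sum(m < 0 | m > clip_upper[[j]])
    m <- pmin(pmax(m, 0), clip_upper[[j]])
    colnames(m) <- paste0("rep", seq_len(noise$replicates))
    reps[[j]] <- m
  }
  structure(list(scenario = scenario, t_grid = t_grid,
                 replicates = reps,
                 mean = lapply(reps, rowMeans),
                 clean = clean,
                 truth = coef(dox_model(scenario)),
                 noise = noise, clipped = clipped),
            class = "dox_dataset")
}

#' Generate a synthetic cell-free dataset
#'
#' Emulates the published reaction-mixture measurements: max-normalized
#' quinone doxorubicin and NADPH on the 11-point grid 0, 2, ..., 20 minutes,
#' with seeded replicate noise, clipped to the normalized assay range
#' [0, 1.05].
#'
#' @param scenario a [dox_scenario()] with `kind = "in_vitro"`.
#' @param noise a [dox_noise()].
#' @param t_grid measurement grid, minutes.
#' @return an object of class `dox_dataset`; `$mean` holds the
#'   replicate-averaged series, `$truth` the generating parameters.
#' @export
generate_invitro_dataset <- function(scenario = dox_scenario("in_vitro"),
                                     noise = dox_noise(),
                                     t_grid = seq(0, 20, by = 2)) {
  stopifnot(scenario$kind == "in_vitro")
  obs <- compute_observables(dox_model(scenario), t_grid,
                             observables = c("quinone_dox", "nadph"))
  clean <- list(
    quinone_dox = obs$values$quinone_dox / max(obs$values$quinone_dox),
    nadph = obs$values$nadph / max(obs$values$nadph))
  .synth_dataset(scenario, t_grid, clean, noise,
                 clip_upper = list(quinone_dox = 1.05, nadph = 1.05))
}

#' Generate a synthetic cell-based dataset
#'
#' Emulates the published cellular readouts on the 7-point grid 0, 10, ...,
#' 60 minutes: intracellular quinone accumulation (M), NADPH fraction of
#' basal, cumulative superoxide signal (normalized to its 60-minute
#' maximum), and extracellular drug depletion (M), with seeded replicate
#' noise. Negative noisy values are clipped at zero.
#'
#' @param scenario a [dox_scenario()] with `kind = "in_vivo"`.
#' @param noise a [dox_noise()].
#' @param t_grid measurement grid, minutes.
#' @return a `dox_dataset`.
#' @export
generate_invivo_dataset <- function(scenario = dox_scenario("in_vivo"),
                                    noise = dox_noise(),
                                    t_grid = seq(0, 60, by = 10)) {
  stopifnot(scenario$kind == "in_vivo")
  obs <- compute_observables(dox_model(scenario), t_grid,
                             observables = c("quinone_dox", "nadph",
                                             "superoxide_signal",
                                             "extracellular_dox"))
  clean <- as.list(obs$values)
  clip <- list(quinone_dox = Inf, nadph = 1.05, superoxide_signal = 1.05,
               extracellular_dox = Inf)
  .synth_dataset(scenario, t_grid, clean, noise, clip_upper = clip)
}

#' Simulate replicate datasets from a model
#'
#' `simulate` draws `nsim` independent synthetic datasets from the model
#' under its scenario conditions (the method behind
#' [generate_invitro_dataset()] / [generate_invivo_dataset()], exposed in
#' the usual modelling idiom).
#'
#' @param object a `dox_model`.
#' @param nsim number of datasets.
#' @param seed RNG seed for the first dataset; dataset i uses `seed + i - 1`.
#' @param sigma,replicates noise settings per dataset.
#' @param ... unused.
#' @return a list of `dox_dataset` objects (length-1 list when `nsim = 1`).
#' @export
simulate.dox_model <- function(object, nsim = 1, seed = 1L, sigma = 0.02,
                               replicates = 3, ...) {
  gen <- if (object$scenario$kind == "in_vitro") generate_invitro_dataset
         else generate_invivo_dataset
  lapply(seq_len(nsim) - 1L, function(i)
    gen(object$scenario, dox_noise(sigma, replicates, seed + i)))
}

#' @export
print.dox_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset (%s): %d observables x %d points x %d replicates\n",
              x$scenario$kind, length(x$replicates), length(x$t_grid),
              x$noise$replicates))
  cat(sprintf("  sigma = %g (seed %d), %d values clipped\n", x$noise$sigma,
              x$noise$seed, x$clipped))
  cat("  observables:", paste(names(x$replicates), collapse = ", "), "\n")
  invisible(x)
}
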