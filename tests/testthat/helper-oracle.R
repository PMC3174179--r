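# Independent oracles, written as direct formula transcriptions of the
# published reaction tables (plus this package's documented stoichiometry
# conventions), deliberately not sharing code with the network engine.

# Cell-free model: 9 coupled equations.
oracle_invitro_rhs <- function(y, k1 = 1.2e4, k2 = k1, k3 = 3.0e8,
                               k4 = 2.9e1, k5 = 5.5e7, k6 = 6.4e9,
                               k_sod = 2e9, sod = 0) {
  y <- pmax(y, 0)
  r1 <- k1 * y[["CPR_red"]] * y[["Dox_q"]]
  r2 <- k2 * y[["CPR_ox"]] * y[["NADPH"]]
  r3 <- k3 * y[["O2"]] * y[["Dox_sq"]]
  r4 <- k4 * y[["NADPH"]] * y[["O2"]]
  r5 <- k5 * y[["O2minus"]] * y[["Dox_q"]]
  r6 <- k6 * y[["O2minus"]]^2
  rs <- k_sod * sod * y[["O2minus"]]
  c(CPR_red = -r1 + r2,
    CPR_ox  =  r1 - r2,
    Dox_q   = -r1 + r3 - r5,
    Dox_sq  =  r1 - r3 + r5,
    NADPH   = -r2 - r4,
    NADP    =  r2 + r4,
    O2      = -r3 - r4 + r5 + 0.5 * rs,
    O2minus =  r3 + r4 - r5 - 2 * r6 - rs,
    H2O2    =  r6 + 0.5 * rs)
}

# Cell model: 10 coupled equations; O2 derivative is zero when clamped.
oracle_invivo_rhs <- function(y, k1 = 1.2e4, k2 = k1, k3 = 3.0e5,
                              k4 = 4.2e4, k5 = 5.5e7, k6 = 6.4e9,
                              k7 = 1.1e-6, A = 6.15, k8 = 1.8e-6,
                              k9 = 5.7e-5, k_dox = 1e-7, vol_ratio = 1e4,
                              o2_clamp = 1.5e-9) {
  y <- pmax(y, 0)
  if (!is.null(o2_clamp)) y[["O2"]] <- o2_clamp
  mod <- y[["In_Dox_q"]] / (y[["In_Dox_q"]] + k_dox)
  r1 <- k1 * y[["CPR_red"]] * y[["In_Dox_q"]]
  r2 <- k2 * y[["CPR_ox"]] * y[["NADPH"]]
  r3 <- k3 * y[["O2"]] * y[["In_Dox_sq"]]
  r4 <- k4 * y[["NADPH"]] * y[["O2"]] * mod
  r5 <- k5 * y[["O2minus"]] * y[["In_Dox_q"]]
  r6 <- k6 * y[["O2minus"]]^2
  r7 <- k7 * A * y[["Ex_Dox_q"]]
  r8 <- k8 * y[["NADP"]] / (k9 + y[["NADP"]])
  c(CPR_red  = -r1 + r2,
    CPR_ox   =  r1 - r2,
    Ex_Dox_q = -r7,
    In_Dox_q =  vol_ratio * r7 - r1 + r3 - r5,
    In_Dox_sq = r1 - r3 + r5,
    NADPH    = -r2 - r4 + r8,
    NADP     =  r2 + r4 - r8,
    O2       = if (is.null(o2_clamp)) -r3 - r4 + r5 + r6 else 0,
    O2minus  =  r3 + r4 - r5 - 2 * r6,
    H2O2     =  r6)
}

# Classical fixed-step 4th-order Runge-Kutta reference integrator.
rk4_integrate <- function(y0, rhs, t_end_sec, dt) {
  y <- y0
  n <- round(t_end_sec / dt)
  for (i in seq_len(n)) {
    k1 <- rhs(y)
    k2 <- rhs(y + dt / 2 * k1)
    k3 <- rhs(y + dt / 2 * k2)
    k4 <- rhs(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

random_state <- function(species, seed) {
  set.seed(seed)
  s <- 10^stats::runif(length(species), -11, -3.5)
  names(s) <- species
  s
}

# Study-condition scenarios used across tests.
sc_redox <- function(...) dox_scenario("in_vitro", nadph0 = 1e-4, ...)
sc_conv <- function(...) dox_scenario("in_vitro", nadph0 = 5e-4, ...)
sc_sod <- function(...) dox_scenario("in_vitro", nadph0 = 5e-4, sod = TRUE,
                                     ...)

noiseless_invitro_datasets <- function(seed = 1) {
  list(redox_cycling = generate_invitro_dataset(sc_redox(),
                                                dox_noise(0, 1, seed)),
       reductive_conversion = generate_invitro_dataset(sc_conv(),
                                                       dox_noise(0, 1, seed)),
       sod_redox_cycling = generate_invitro_dataset(sc_sod(),
                                                    dox_noise(0, 1, seed)))
}

noiseless_invivo_datasets <- function(seed = 1) {
  eu1 <- generate_invivo_dataset(dox_scenario("in_vivo"),
                                 dox_noise(0, 1, seed))
  list(extracellular_depletion = eu1, nadph_depletion = eu1)
}

# Toy single-reaction models assembled directly from the network layer.
# First-order transfer of extracellular drug into the cell; with
# `clamp_source = TRUE` the source pool is held constant, making the
# 60-minute uptake readout exactly linear in the rate constant.
toy_transfer_model <- function(k = 1e-4, A = 1, vol_ratio = 1,
                               ex0 = 1e-5, clamp_source = FALSE,
                               extra_supply = FALSE) {
  species <- c("CPR_red", "CPR_ox", "Ex_Dox_q", "In_Dox_q", "In_Dox_sq",
               "NADPH", "NADP", "O2", "O2minus", "H2O2")
  rx <- list(dox_reaction("R7", "permeation", "k7",
                          reactants = c(Ex_Dox_q = 1), factor = "A",
                          consumes = c(Ex_Dox_q = 1),
                          produces = c(In_Dox_q = vol_ratio)))
  if (extra_supply)
    rx <- c(rx, list(dox_reaction("R8", "saturable_supply", "k8", km = "k9",
                                  reactants = c(NADP = 1),
                                  consumes = c(NADP = 1),
                                  produces = c(NADPH = 1))))
  state0 <- c(CPR_red = 0, CPR_ox = 0, Ex_Dox_q = ex0, In_Dox_q = 0,
              In_Dox_sq = 0, NADPH = 1e-5, NADP = 1e-7, O2 = 0,
              O2minus = 0, H2O2 = 0)
  structure(list(
    network = dox_network(species, rx),
    params = c(k7 = k, A = A, k8 = 1e-7, k9 = 5.7e-5, vol_ratio = vol_ratio),
    state0 = state0,
    clamp = if (clamp_source) c(Ex_Dox_q = ex0) else NULL,
    scenario = dox_scenario("in_vivo", strict = FALSE)),
    class = "dox_model")
}
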