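test_that("trajectories start at the initial conditions and conserve moieties", {
  m <- build_invitro_model()
  tc <- simulate_timecourse(m, seq(0, 20, by = 2))
  expect_equal(unlist(tc$values[1, ]), m$state0)

  # conservation to well within 10x the integrator tolerance budget
  tol <- 10 * (1e-8 * max(m$state0) + 1e-14)
  cpr_tot <- tc$values$CPR_red + tc$values$CPR_ox
  expect_lt(max(abs(cpr_tot - cpr_tot[1])), tol)
  nad_tot <- tc$values$NADPH + tc$values$NADP
  expect_lt(max(abs(nad_tot - nad_tot[1])), tol)

  mv <- build_invivo_model()
  tcv <- simulate_timecourse(mv, seq(0, 60, by = 5))
  phi <- 1 / mv$params[["vol_ratio"]]
  dox_tot <- tcv$values$Ex_Dox_q +
    phi * (tcv$values$In_Dox_q + tcv$values$In_Dox_sq)
  expect_lt(max(abs(dox_tot - dox_tot[1])), 10 * (1e-8 * 1e-5 + 1e-14))
  cpr_tot <- tcv$values$CPR_red + tcv$values$CPR_ox
  expect_lt(max(abs(cpr_tot - cpr_tot[1])), tol)
})

test_that("stiff solution matches a fixed-step 4th-order reference", {
  # the fastest relaxation (semiquinone re-oxidation, ~8e4 per second)
  # bounds the explicit step: dt = 2e-5 s keeps RK4 inside its stability
  # region, so the window is kept short
  m <- build_invitro_model()
  t_end <- 1  # seconds
  ref <- rk4_integrate(m$state0, function(y) oracle_invitro_rhs(y),
                       t_end_sec = t_end, dt = 2e-5)
  got <- unlist(simulate_timecourse(m, c(0, t_end / 60))$values[2, ])
  big <- ref > 1e-12
  expect_lt(max(abs(got[big] - ref[big]) / ref[big]), 1e-4)
  if (any(!big)) expect_lt(max(abs(got[!big] - ref[!big])), 1e-12)
})

test_that("reported observables are stable under tolerance refinement", {
  m <- build_invivo_model()
  o1 <- compute_observables(m, seq(0, 60, by = 10), dense_dt = 0.2)
  o2 <- compute_observables(m, seq(0, 60, by = 10), dense_dt = 0.2,
                            rtol = 0.5e-8, atol = 0.5e-14)
  for (j in names(o1$values)) {
    scale <- max(abs(o1$values[[j]]))
    expect_lt(max(abs(o1$values[[j]]- o2$values[[j]])) / scale, 1e-3)
  }
})

test_that("observable mappings honour their normalization contracts", {
  m <- build_invivo_model()
  obs <- compute_observables(m, seq(0, 60, by = 10), dense_dt = 0.2)
  expect_equal(obs$values$nadph[1], 1.0)          # fraction of basal
  expect_true(all(diff(obs$values$superoxide_signal) >= 0))
  expect_equal(max(obs$values$superoxide_signal), 1.0) # max-normalized
  expect_equal(obs$values$extracellular_dox[1], 1e-5)  # raw molar
  expect_error(compute_observables(m, 0:6, observables = "nope"),
               "unknown observable")
  # a max-normalized synthetic series has maximum exactly one
  ds <- generate_invitro_dataset(sc_redox(), dox_noise(0, 1, 1))
  expect_equal(max(ds$mean$quinone_dox), 1.0)
})

test_that("integrated fluxes: degenerate windows, initial condition, closed form", {
  m <- build_invivo_model()
  tc <- simulate_timecourse(m, seq(0, 60, by = 0.5))
  expect_equal(integrated_flux(m, tc, "R1", c(10, 10)), 0)
  expect_error(integrated_flux(m, tc, "R1", c(0, 90)), "window")
  expect_error(integrated_flux(m, tc, "nope"), "unknown reaction")
  # no intracellular drug at t = 0, so the early semiquinone flux vanishes
  # quadratically with the window length
  tc_early <- simulate_timecourse(m, seq(0, 0.05, length.out = 11))
  early <- integrated_flux(m, tc_early, "R1", c(0, 0.05))
  full <- integrated_flux(m, tc, "R1", c(0, 60))
  expect_lt(early, 1e-3 * full)

  # first-order toy: integral = Ex0 (1 - exp(-kAT)), and halving the rate
  # while doubling the window leaves it invariant
  k <- 1e-4; T1 <- 60
  toy <- toy_transfer_model(k = k)
  tct <- simulate_timecourse(toy, seq(0, T1, by = 0.25))
  got <- integrated_flux(toy, tct, "R7", c(0, T1))
  expect_equal(got, 1e-5 * (1 - exp(-k * T1 * 60)), tolerance = 1e-5)
  toy2 <- toy_transfer_model(k = k / 2)
  tct2 <- simulate_timecourse(toy2, seq(0, 2 * T1, by = 0.5))
  expect_equal(integrated_flux(toy2, tct2, "R7", c(0, 2 * T1)), got,
               tolerance = 1e-5)
})

test_that("time-course container validates its grid and converts to long form", {
  expect_error(dox_timecourse(c(0, 2, 2), data.frame(a = 1:3)),
               "strictly increasing")
  expect_error(dox_timecourse(c(0, 2), data.frame(a = 1:3)), "length")
  tc <- dox_timecourse(c(0, 5), data.frame(b = c(1, 2), a = c(3, 4)))
  long <- as.data.frame(tc)
  expect_equal(names(long),
               c("time_min", "series", "value", "units", "normalization"))
  expect_equal(long$series, c("a", "a", "b", "b"))  # canonical sort
})

test_that("predict returns observables or species", {
  m <- build_invitro_model()
  p1 <- predict(m, t_grid = seq(0, 20, by = 10))
  expect_s3_class(p1, "dox_timecourse")
  expect_true(all(c("quinone_dox", "nadph") %in% names(p1$values)))
  p2 <- predict(m, t_grid = seq(0, 20, by = 10), type = "species")
  expect_equal(names(p2$values), m$network$species)
})
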