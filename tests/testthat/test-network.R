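test_that("rate laws reproduce hand-computed values and limits", {
  m <- build_invitro_model()
  # k1 * [CPR_red] * [Dox_q] at the published initial concentrations
  expect_equal(evaluate_rates(m)[["R1"]], 1.2e4 * 1.0e-6 * 1.0e-4)
  expect_equal(evaluate_rates(m)[["R1"]], 1.2e-6)

  # any reaction with a reactant at zero has rate zero
  s <- m$state0
  s[["CPR_red"]] <- 0
  expect_equal(evaluate_rates(m, s)[["R1"]], 0)
  expect_equal(unname(evaluate_rates(m, m$state0)[c("R2", "R3", "R5", "R6")]),
               rep(0, 4))

  # the saturable supply tends to its maximal rate as [NADP] grows
  mv <- build_invivo_model()
  s <- mv$state0
  s[["NADP"]] <- 1e3  # [NADP] >> k9
  expect_equal(evaluate_rates(mv, s)[["R8"]], mv$params[["k8"]],
               tolerance = 1e-6)
})

test_that("configuration errors name the missing symbol", {
  m <- build_invitro_model()
  s <- m$state0
  expect_error(evaluate_rates(m, s[-1]), "CPR_red")
  m2 <- m
  m2$params <- m2$params[setdiff(names(m2$params), "k3")]
  expect_error(evaluate_rates(m2, s), "k3")
  expect_error(
    dox_network("A", list(dox_reaction("R1", "bimolecular_mass_action",
                                       "k", c(B = 1)))),
    "unknown species: B")
})

test_that("engine RHS matches the independent transcription at random states", {
  m_vitro <- build_invitro_model(sc_sod())
  m_vivo <- build_invivo_model()
  m_vivo_dyn <- build_invivo_model(dox_scenario("in_vivo",
                                                oxygen_clamp = FALSE))
  for (i in 1:20) {
    s9 <- random_state(m_vitro$network$species, 1000 + i)
    ref <- oracle_invitro_rhs(s9, sod = m_vitro$params[["sod_conc"]])
    expect_equal(evaluate_rhs(m_vitro, s9), ref, tolerance = 1e-12)

    s10 <- random_state(m_vivo$network$species, 2000 + i)
    expect_equal(evaluate_rhs(m_vivo, s10),
                 oracle_invivo_rhs(s10, o2_clamp = 1.5e-9),
                 tolerance = 1e-12)
    expect_equal(evaluate_rhs(m_vivo_dyn, s10),
                 oracle_invivo_rhs(s10, o2_clamp = NULL),
                 tolerance = 1e-12)
  }
})

test_that("compiled integrator RHS agrees with the generic engine", {
  for (m in list(build_invitro_model(sc_sod()), build_invivo_model())) {
    f <- doxcycle:::.compile_model(m)
    for (i in 1:10) {
      s <- random_state(m$network$species, 3000 + i)
      expect_equal(unname(f(0, s, NULL)[[1]]), unname(evaluate_rhs(m, s)),
                   tolerance = 1e-12)
    }
  }
})

test_that("stoichiometry matrix has the model dimensions and generates the RHS", {
  m9 <- build_invitro_model()
  m10 <- build_invivo_model(dox_scenario("in_vivo", oxygen_clamp = FALSE))
  S9 <- stoichiometry_matrix(m9)
  S10 <- stoichiometry_matrix(m10)
  expect_equal(nrow(S9), 9)   # 9 coupled equations, cell-free model
  expect_equal(nrow(S10), 10) # 10 coupled equations, cell model
  for (i in 1:5) {
    s <- random_state(m9$network$species, 4000 + i)
    expect_equal(drop(S9 %*% evaluate_rates(m9, s)), evaluate_rhs(m9, s))
    s <- random_state(m10$network$species, 5000 + i)
    expect_equal(drop(S10 %*% evaluate_rates(m10, s)),
                 evaluate_rhs(m10, s))
  }
})

test_that("moiety and drug totals are conserved by the RHS", {
  m9 <- build_invitro_model()
  m10 <- build_invivo_model()
  for (i in 1:10) {
    d <- evaluate_rhs(m9, random_state(m9$network$species, 6000 + i))
    expect_equal(d[["CPR_red"]] + d[["CPR_ox"]], 0)
    expect_equal(d[["NADPH"]] + d[["NADP"]], 0)
    expect_equal(d[["Dox_q"]] + d[["Dox_sq"]], 0)

    s <- random_state(m10$network$species, 7000 + i)
    d <- evaluate_rhs(m10, s)
    expect_equal(d[["CPR_red"]] + d[["CPR_ox"]], 0)
    expect_equal(d[["NADPH"]] + d[["NADP"]], 0)
    # total drug: extracellular pool + cytosolic pools weighted by the
    # cytosolic volume fraction
    phi <- 1 / m10$params[["vol_ratio"]]
    expect_equal(d[["Ex_Dox_q"]] +
                   phi * (d[["In_Dox_q"]] + d[["In_Dox_sq"]]), 0,
                 tolerance = 1e-12)
  }
})

test_that("rates are non-negative on the non-negative orthant", {
  m <- build_invivo_model()
  for (i in 1:10) {
    s <- random_state(m$network$species, 8000 + i)
    expect_true(all(evaluate_rates(m, s) >= 0))
  }
  # slight integrator overshoot below zero is clamped in rate evaluation
  s <- m$state0
  s[["In_Dox_q"]] <- -1e-15
  expect_true(all(evaluate_rates(m, s) >= 0))
})
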