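test_that("noiseless generation equals the model prediction on the assay grids", {
  ds <- generate_invitro_dataset(sc_redox(), dox_noise(0, 3, 1))
  expect_length(ds$t_grid, 11)               # 0, 2, ..., 20 min
  expect_equal(ds$t_grid, seq(0, 20, by = 2))
  for (j in names(ds$mean)) {
    expect_equal(ds$mean[[j]], ds$clean[[j]])
    expect_true(all(ds$replicates[[j]] == ds$clean[[j]]))
  }

  dv <- generate_invivo_dataset(dox_scenario("in_vivo"), dox_noise(0, 3, 1))
  expect_length(dv$t_grid, 7)                # 0, 10, ..., 60 min
  expect_equal(dv$t_grid, seq(0, 60, by = 10))
  expect_equal(dv$mean$nadph[1], 1.0)        # fraction of basal before noise
  expect_setequal(names(dv$mean),
                  c("quinone_dox", "nadph", "superoxide_signal",
                    "extracellular_dox"))
  # generating parameters are recorded verbatim for recovery tests
  expect_identical(dv$truth, coef(dox_model(dv$scenario)))
})

test_that("identical seeds give bit-identical datasets; clipping is bounded", {
  a <- generate_invitro_dataset(sc_conv(), dox_noise(0.05, 3, 42))
  b <- generate_invitro_dataset(sc_conv(), dox_noise(0.05, 3, 42))
  expect_identical(a$replicates, b$replicates)
  c <- generate_invitro_dataset(sc_conv(), dox_noise(0.05, 3, 43))
  expect_false(identical(a$replicates, c$replicates))
  # normalized assay range
  for (j in names(a$replicates)) {
    expect_true(all(a$replicates[[j]] >= 0))
    expect_true(all(a$replicates[[j]] <= 1.05))
  }
})

test_that("simulate() draws independent replicate datasets from a model", {
  m <- build_invitro_model()
  sims <- simulate(m, nsim = 2, seed = 7, sigma = 0.02)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "dox_dataset")
  expect_false(identical(sims[[1]]$replicates, sims[[2]]$replicates))
  expect_identical(sims[[1]]$replicates,
                   simulate(m, nsim = 1, seed = 7, sigma = 0.02)[[1]]$replicates)
})

test_that("the resistant line accumulates more quinone drug at the high dose", {
  eu1 <- generate_invivo_dataset(dox_scenario("in_vivo",
                                              cell_line = "EU1-Res"),
                                 dox_noise(0.02, 3, 9))
  eu3 <- generate_invivo_dataset(dox_scenario("in_vivo",
                                              cell_line = "EU3-Sens"),
                                 dox_noise(0.02, 3, 9))
  expect_gt(ds_end <- eu1$mean$quinone_dox[7], eu3$mean$quinone_dox[7])
})

test_that("replicate standard error shrinks roughly as one over root n", {
  se_of <- function(reps) {
    m <- generate_invitro_dataset(sc_redox(), dox_noise(0.05, reps, 21))
    mean(vapply(m$replicates, function(x)
      mean(apply(x, 1, stats::sd) / sqrt(ncol(x))), numeric(1)))
  }
  ratio <- se_of(3) / se_of(12)
  expect_gt(ratio, 1.4)   # expected factor 2 (x 4 replicates)
  expect_lt(ratio, 2.8)
})

test_that("noisy recovery of the identifiable constants stays within 15% (median)", {
  ## 2% assay noise, 3 replicates, 20 seeds; k1 and k4 from the cell-free
  ## stages, k8 from the cellular NADPH-depletion stage. The SOD-stage k5
  ## and the permeability k7 are excluded: their data carry too little
  ## signal at this noise level (near-flat cost above the true k5; a ~2.4%
  ## extracellular depletion against a 2% noise floor).
  errs <- list(k1 = c(), k4 = c(), k8 = c())
  for (s in 1:20) {
    vitro <- list(
      redox_cycling = generate_invitro_dataset(sc_redox(),
                                               dox_noise(0.02, 3, 100 + s)),
      reductive_conversion = generate_invitro_dataset(
        sc_conv(), dox_noise(0.02, 3, 200 + s)))
    pl <- suppressWarnings(run_fit_pipeline("in_vitro", vitro))
    eu1 <- generate_invivo_dataset(dox_scenario("in_vivo"),
                                   dox_noise(0.02, 3, 300 + s))
    pv <- run_fit_pipeline("in_vivo",
                           list(extracellular_depletion = eu1,
                                nadph_depletion = eu1))
    est <- c(coef(pl), coef(pv))
    truth <- c(k1 = 1.2e4, k4 = 2.9e1, k8 = 1.8e-6)
    for (p in names(errs))
      errs[[p]] <- c(errs[[p]], abs(est[[p]] - truth[[p]]) / truth[[p]])
  }
  meds <- vapply(errs, stats::median, numeric(1))
  expect_lt(meds[["k1"]], 0.15)
  expect_lt(meds[["k4"]], 0.15)
  expect_lt(meds[["k8"]], 0.15)
})
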