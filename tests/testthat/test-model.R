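test_that("derivatives vanish without populations or medium", {
  v <- reference_variant()
  p <- reference_parameters()
  zero <- setNames(numeric(10), copred_state_names())
  expect_equal(predation_derivatives(v, p, zero), zero)

  # prey without medium or predators neither grows nor dies
  s <- zero
  s["N_S"] <- 1e8
  d <- predation_derivatives(v, p, s)
  expect_equal(unname(d["N_S"]), 0)
  expect_true(all(d == 0))
})

test_that("derivatives match an independent flux-ledger oracle", {
  set.seed(401)
  for (v in some_variants()) {
    for (rep in 1:5) {
      p <- draw_from_prior(v)
      s <- random_state(v, scale = 10^runif(1, 3, 9))
      got <- predation_derivatives(v, p, s)
      want <- oracle_derivs(v, p, s)
      expect_equal(got, want, tolerance = 1e-12,
                   label = paste("derivatives for", variant_label(v)))
    }
  }
})

test_that("derivatives reject invalid states", {
  v <- reference_variant()
  p <- reference_parameters()
  s <- random_state(v, seed = 1)
  s["N_S"] <- -5
  expect_error(predation_derivatives(v, p, s), "non-negative")
  s2 <- random_state(model_variant("N1"), seed = 2)
  s2["N_P"] <- 100  # excluded under N1
  expect_error(predation_derivatives(model_variant("N1"), p, s2), "excluded")
})

test_that("initial states implement the condition layout", {
  p <- parameter_set(f_R = 0)
  s <- initial_state(p, "prey_only")
  expect_equal(unname(s["N_S"]), p$N0)
  expect_equal(unname(s["P"]), 0)
  expect_equal(unname(s["V"]), 0)
  expect_equal(unname(s["M"]), p$M0)
  expect_true(all(s[c("N_P", "N_R", "N_D", "B", "I", "C")] == 0))

  p2 <- parameter_set(N0 = 2.9e8, P0 = 2.8e6, V0 = 3.7e6, f_R = 2.6e-6)
  s2 <- initial_state(p2, "dual")
  expect_equal(unname(s2["N_S"] + s2["N_R"]), 2.9e8)
  expect_equal(unname(s2["P"]), 2.8e6)
  expect_equal(unname(s2["V"]), 3.7e6)
  # the preexisting resistant subpopulation: f_R * N0 = 754 cells/ml
  expect_equal(unname(s2["N_R"]), 2.6e-6 * 2.9e8)
  expect_equal(unname(s2["N_R"]), 754, tolerance = 1e-12)

  # without an N_R compartment all prey start sensitive
  s3 <- initial_state(p2, "dual", model_variant("N1"))
  expect_equal(unname(s3["N_S"]), 2.9e8)
  expect_equal(unname(s3["N_R"]), 0)
})

test_that("observables sum the plaque- and colony-forming compartments", {
  tr <- simulate_predation(reference_variant(), reference_parameters(),
                           condition = "dual", times = seq(0, 10, 1))
  ob <- observables(tr)
  expect_equal(ob$prey, tr$N_S + tr$N_P + tr$N_R + tr$N_D)
  expect_equal(ob$bdellovibrio, tr$P + tr$B)
  expect_equal(ob$phage, tr$V + tr$I)
  # intracellular stages at zero collapse the counts onto the free forms
  expect_equal(ob$bdellovibrio[1], tr$P[1])
  expect_equal(ob$phage[1], tr$V[1])
})

test_that("without predation, predators are constant and prey + medium is conserved", {
  v <- reference_variant()
  p <- parameter_set(a_P = 0, a_V = 0, d_P = 0)
  tr <- simulate_predation(v, p, condition = "dual", times = seq(0, 48, 2))
  expect_equal(tr$P, rep(p$P0, nrow(tr)), tolerance = 1e-8)
  expect_equal(tr$V, rep(p$V0, nrow(tr)), tolerance = 1e-8)
  total <- tr$N_S + tr$N_P + tr$N_R + tr$N_D + tr$M
  expect_equal(total, rep(total[1], nrow(tr)), tolerance = 1e-8)
})

test_that("predator-free growth matches the exponential closed form", {
  # K_M >> M0 and N0 << M0 keep the Monod factor effectively constant,
  # so N(t) = N0 exp(mu_eff t) with mu_eff = mu_max M0 / (K_M + M0)
  p <- parameter_set(f_R = 0, m = 0, K_M = 1e10, M0 = 1e9, N0 = 1e4)
  mu_eff <- p$mu_max * p$M0 / (p$K_M + p$M0)
  tr <- simulate_predation(reference_variant(), p, condition = "prey_only",
                           times = seq(0, 10, 0.5))
  expect_equal(tr$N_S, p$N0 * exp(mu_eff * tr$time_h), tolerance = 1e-6)
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle", {
  v <- reference_variant()
  p <- reference_parameters()
  times <- seq(0, 10, 2)
  tr <- simulate_predation(v, p, condition = "dual", times = times)
  ork <- oracle_rk4(v, p, initial_state(p, "dual", v), times, h = 1e-3)
  for (comp in copred_state_names()) {
    a <- tr[[comp]]
    b <- ork[, comp]
    big <- pmax(a, b) > 1e-6
    if (any(big)) {
      expect_equal(a[big], b[big], tolerance = 1e-6,
                   label = paste("compartment", comp))
    }
  }
})

test_that("oracle agreement holds across random prior draws at reduced densities", {
  set.seed(77)
  v <- reference_variant()
  times <- seq(0, 5, 1)
  for (rep in 1:8) {
    p <- parameter_set(base = draw_from_prior(v),
                       N0 = 1e6, P0 = 1e4, V0 = 1e4, M0 = 1e6)
    tr <- simulate_predation(v, p, condition = "dual", times = times)
    ork <- oracle_rk4(v, p, initial_state(p, "dual", v), times, h = 1e-3)
    for (comp in copred_state_names()) {
      a <- tr[[comp]]
      b <- ork[, comp]
      big <- pmax(a, b) > 1e-6
      if (any(big)) {
        expect_equal(a[big], b[big], tolerance = 1e-5,
                     label = paste("draw", rep, "compartment", comp))
      }
    }
  }
})

test_that("trajectories stay non-negative for random prior draws", {
  set.seed(88)
  v <- reference_variant()
  for (rep in 1:25) {
    p <- draw_from_prior(v)
    tr <- tryCatch(
      simulate_predation(v, p, condition = "dual", times = seq(0, 48, 2)),
      copred_integration_error = function(e) NULL
    )
    if (!is.null(tr)) {
      expect_true(all(as.matrix(tr[copred_state_names()]) >= 0))
    }
  }
})

test_that("the nested variants collapse onto each other when rates are zeroed", {
  times <- seq(0, 48, 4)
  p0 <- reference_parameters()

  # N4 -> N3: no flux generates N_D once mutation and conversion are off
  p_nd <- parameter_set(base = p0, m = 0, k_sig = 0, sigma_C = 0)
  t4 <- simulate_predation(model_variant("N4", conversion = "SG",
                                         signal_source = "B_only"),
                           p_nd, condition = "dual", times = times)
  t3 <- simulate_predation(reference_variant(), p_nd, condition = "dual",
                           times = times)
  expect_equal(as.matrix(t4[copred_state_names()]),
               as.matrix(t3[copred_state_names()]), tolerance = 1e-8)
  expect_true(all(t4$N_D == 0))

  # N3 -> N2: conversion off leaves N_P empty
  p_np <- parameter_set(base = p0, k_sig = 0, sigma_C = 0)
  t3b <- simulate_predation(reference_variant(), p_np, condition = "dual",
                            times = times)
  t2 <- simulate_predation(model_variant("N2"), p_np, condition = "dual",
                           times = times)
  keep32 <- setdiff(copred_state_names(), c("N_P", "C"))
  expect_equal(as.matrix(t3b[keep32]), as.matrix(t2[keep32]), tolerance = 1e-8)
  expect_true(all(t3b$N_P == 0))

  # N2 -> N1: no preexisting or de novo resistance leaves N_R empty
  p_nr <- parameter_set(base = p0, f_R = 0, m = 0)
  t2b <- simulate_predation(model_variant("N2"), p_nr, condition = "dual",
                            times = times)
  t1 <- simulate_predation(model_variant("N1"), p_nr, condition = "dual",
                           times = times)
  keep21 <- setdiff(copred_state_names(), "N_R")
  expect_equal(as.matrix(t2b[keep21]), as.matrix(t1[keep21]), tolerance = 1e-8)
  expect_true(all(t2b$N_R == 0))
})

test_that("prey killed by each predator equals the influx into the intracellular pools", {
  # with resolution and mortality switched off, B and I accumulate exactly
  # the prey each predator removed
  v <- reference_variant()
  p <- parameter_set(k_B = 0, k_I = 0, d_P = 0, k_sig = 0, sigma_C = 0, m = 0)
  times <- seq(0, 12, 0.5)
  tr <- simulate_predation(v, p, condition = "dual", times = times)
  prey_lost <- (tr$N_S + tr$N_P + tr$N_R + tr$N_D + tr$M)[1] -
    (tr$N_S + tr$N_P + tr$N_R + tr$N_D + tr$M)
  expect_equal(tr$B + tr$I, prey_lost, tolerance = 1e-6)
})
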