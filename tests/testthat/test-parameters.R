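test_that("parameter validation enforces the biological constraints", {
  expect_error(parameter_set(mu_max = -1), "Negative")
  expect_error(parameter_set(beta_P = 0.5), "Burst")
  expect_error(parameter_set(beta_V = 0), "Burst")
  expect_error(parameter_set(m = 1.5), "m must lie")
  expect_error(parameter_set(f_R = 2), "f_R must lie")
  expect_error(parameter_set(eps_B = 1), "eps_B")
  expect_error(parameter_set(eps_I = 1.2), "eps_B")
  expect_error(parameter_set(nonsense = 1), "Unknown")
  # boundary values that are allowed
  expect_s3_class(parameter_set(m = 0, f_R = 0, eps_B = 0.99), "copred_params")
})

test_that("free parameters track the variant's structure", {
  ref <- free_parameters(reference_variant())
  expect_true(all(c("k_sig", "sigma_C", "f_R", "m", "K_P", "M0") %in% ref))
  expect_false(any(c("r_I", "r_back", "d_P", "K_V", "N0", "P0", "V0") %in% ref))

  fitted <- free_parameters(model_variant("N3", mortality_mode = "fitted"))
  expect_true("d_P" %in% fitted)

  intr <- free_parameters(model_variant("N3", conversion = "I"))
  expect_true(all(c("r_I", "r_back") %in% intr))
  expect_false(any(c("k_sig", "sigma_C") %in% intr))

  sig_intr <- free_parameters(model_variant("N3", conversion = "S"))
  expect_true(all(c("k_sig", "sigma_C", "r_back") %in% sig_intr))

  n1 <- free_parameters(model_variant("N1"))
  expect_false(any(c("f_R", "m", "k_sig", "r_I") %in% n1))

  pre <- free_parameters(model_variant("N2", resistance_origin = "preexisting"))
  expect_true("f_R" %in% pre)
  expect_false("m" %in% pre)
})

test_that("default priors cover exactly the free parameters and pin the rest", {
  for (v in some_variants()) {
    pr <- default_priors(v)
    expect_setequal(pr$bounds$parameter, free_parameters(v))
    expect_setequal(names(pr$fixed),
                    setdiff(copred:::.copred_par_names, free_parameters(v)))
    expect_true(all(pr$bounds$lower < pr$bounds$upper))
  }
})

test_that("prior_spec validates its bounds", {
  expect_error(prior_spec(data.frame(parameter = "x", dist = "normal",
                                     lower = 0, upper = 1)), "dist")
  expect_error(prior_spec(data.frame(parameter = "x", dist = "uniform",
                                     lower = 1, upper = 1)), "lower < upper")
  expect_error(prior_spec(data.frame(parameter = "x", dist = "loguniform",
                                     lower = 0, upper = 1)), "positive")
})
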