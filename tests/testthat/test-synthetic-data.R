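quick_design <- function(...) {
  experiment_design(duration = 12, sampling_interval = 4, ...)
}

test_that("design and noise constructors validate their inputs", {
  expect_error(experiment_design(duration = 0), "positive")
  expect_error(experiment_design(sampling_interval = 5), "divide")
  expect_error(experiment_design(replicates = 0), "replicates")
  expect_error(experiment_design(detection_limit = -1), "detection_limit")
  expect_error(noise_model(log10_sd = -0.1), "log10_sd")
})

test_that("zero noise and zero detection limit reproduce the observables exactly", {
  des <- quick_design(detection_limit = 0, replicates = 2)
  d <- generate_dataset(design = des, noise = noise_model(log10_sd = 0, seed = 5))
  expect_false(any(d$censored))
  truth <- simulated_series(reference_variant(),
                            parameter_set(N0 = des$N0, P0 = des$P0, V0 = des$V0),
                            d)
  joined <- dplyr::left_join(
    d, truth, by = c("condition", "population", "time_h"),
    suffix = c("", "_truth")
  )
  expect_equal(joined$density_per_ml, joined$density_per_ml_truth)
})

test_that("datasets are reproducible from the seed and differ across seeds", {
  des <- quick_design()
  a <- generate_dataset(design = des, noise = noise_model(seed = 11))
  b <- generate_dataset(design = des, noise = noise_model(seed = 11))
  c <- generate_dataset(design = des, noise = noise_model(seed = 12))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(any(a$density_per_ml != c$density_per_ml, na.rm = TRUE))
})

test_that("the default design has the published layout and starting density", {
  d <- generate_dataset(noise = noise_model(seed = 2))
  expect_setequal(unique(d$condition),
                  c("prey_only", "bdellovibrio_only", "phage_only", "dual"))
  expect_equal(sort(unique(d$time_h)), seq(0, 48, 2))
  expect_equal(sort(unique(d$replicate)), 1:3)
  expect_equal(nrow(d), 4 * 3 * 25 * 3)
  prey0 <- d$density_per_ml[d$population == "prey" & d$time_h == 0]
  # every replicate within noise (4 sd on log10) of 2.9e8 CFU/ml
  expect_true(all(abs(log10(prey0) - log10(2.9e8)) < 4 * 0.15))
})

test_that("replicate noise is unbiased on the log10 scale", {
  # grand means over 200 seeded single-condition datasets recover the truth
  des <- experiment_design(duration = 16, sampling_interval = 8,
                           conditions = "dual", detection_limit = 0)
  truth <- simulated_series(
    reference_variant(),
    parameter_set(N0 = des$N0, P0 = des$P0, V0 = des$V0),
    generate_dataset(design = des, noise = noise_model(log10_sd = 0, seed = 1))
  )
  truth <- dplyr::arrange(truth, condition, population, time_h)
  n_sets <- 200
  sums <- 0
  for (s in seq_len(n_sets)) {
    d <- generate_dataset(design = des,
                          noise = noise_model(log10_sd = 0.15, seed = 1000 + s))
    m <- dplyr::summarise(d, lm = mean(log10(density_per_ml)),
                          .by = c(condition, population, time_h))
    m <- dplyr::arrange(m, condition, population, time_h)
    sums <- sums + m$lm
  }
  grand <- sums / n_sets
  se <- 0.15 / sqrt(3 * n_sets)
  z <- (grand - log10(pmax(truth$density_per_ml, 1e-300))) / se
  expect_true(all(abs(z) < 3))
})

test_that("raising the detection limit never decreases censoring", {
  des_lo <- quick_design(detection_limit = 10)
  des_hi <- quick_design(detection_limit = 1e4)
  a <- generate_dataset(design = des_lo, noise = noise_model(seed = 9))
  b <- generate_dataset(design = des_hi, noise = noise_model(seed = 9))
  expect_gte(sum(b$censored), sum(a$censored))
  # censored entries are flags, not zeros
  expect_true(all(is.na(a$density_per_ml[a$censored])))
  expect_true(all(a$density_per_ml[!a$censored] >= 10))
})

test_that("the Poisson small-count option only touches low densities", {
  des <- quick_design(detection_limit = 0)
  d <- generate_dataset(design = des,
                        noise = noise_model(seed = 4, poisson_counts = TRUE))
  low <- d$density_per_ml[d$density_per_ml < 100]
  expect_true(all(low == round(low)))
  high <- d$density_per_ml[d$density_per_ml >= 100]
  expect_false(all(high == round(high)))
})
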