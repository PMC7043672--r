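uni_prior <- function(lower = -10, upper = 10) {
  prior_spec(data.frame(parameter = "theta", dist = "uniform",
                        lower = lower, upper = upper))
}

test_that("prior sampling honours the distribution families", {
  # degenerate-ish prior: a vanishingly narrow box pins the draw
  pr <- prior_spec(data.frame(parameter = c("a", "b"),
                              dist = c("uniform", "loguniform"),
                              lower = c(2, 1e-6), upper = c(2 + 1e-12, 1e-6 * (1 + 1e-12))))
  th <- sample_prior(pr, 1, seed = 1)$theta[[1]]
  expect_equal(unname(th["a"]), 2, tolerance = 1e-9)
  expect_equal(unname(th["b"]), 1e-6, tolerance = 1e-9)

  # log-uniform draws are uniform on the log10 scale (Kolmogorov-Smirnov)
  pr2 <- prior_spec(data.frame(parameter = "k", dist = "loguniform",
                               lower = 1e-9, upper = 1e-5))
  draws <- sample_prior(pr2, 1e4, seed = 2)
  lg <- log10(vapply(draws$theta, `[[`, numeric(1), "k"))
  ks <- suppressWarnings(stats::ks.test(lg, "punif", -9, -5))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(lg >= -9 & lg <= -5))
})

test_that("the model index is uniform over the candidate models", {
  priors <- list(A = uni_prior(), B = uni_prior())
  draws <- sample_prior(priors, 1e4, seed = 3)
  fA <- mean(draws$model == "A")
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(fA - 0.5), 3 * se)
})

test_that("perturbation respects the kernel scale and the prior support", {
  pr <- prior_spec(data.frame(parameter = c("a", "k"),
                              dist = c("uniform", "loguniform"),
                              lower = c(0, 1e-8), upper = c(1, 1e-2)))
  th <- c(a = 0.4, k = 1e-5)
  # zero scale returns the particle unchanged
  expect_equal(perturb_particle(th, pr, c(a = 0, k = 0)), th)

  # all perturbations stay inside the support
  set.seed(5)
  props <- replicate(2000, perturb_particle(th, pr, c(a = 0.5, k = 1.5)))
  expect_true(all(props["a", ] >= 0 & props["a", ] <= 1))
  expect_true(all(props["k", ] >= 1e-8 & props["k", ] <= 1e-2))
})

test_that("perturbed clouds add the kernel variance", {
  # wide support so that truncation is negligible
  pr <- uni_prior(-100, 100)
  set.seed(6)
  src <- rnorm(4000, 0, 1)
  sd_k <- 0.7
  pert <- vapply(src, function(x) {
    perturb_particle(c(theta = x), pr, c(theta = sd_k))[["theta"]]
  }, numeric(1))
  expect_equal(var(pert), var(src) + sd_k^2, tolerance = 0.1)
})

test_that("an infinite-tolerance run reproduces the prior", {
  model <- list(flat = list(
    prior = uni_prior(-5, 5),
    distance = function(th) abs(th[["theta"]])
  ))
  res <- abc_smc(model, smc_config(n_particles = 400, max_generations = 1,
                                   eps_init = Inf, seed = 7))
  td <- tidy(res)
  expect_equal(nrow(td), 400)
  expect_equal(sum(td$weight), 1)
  ks <- suppressWarnings(stats::ks.test(td$theta, "punif", -5, 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("tolerances decrease strictly and weights stay normalized", {
  model <- list(norm = list(
    prior = uni_prior(),
    distance = function(th) abs(mean(rnorm(20, th[["theta"]], 1)) - 2)
  ))
  res <- abc_smc(model, smc_config(n_particles = 150, max_generations = 5,
                                   seed = 8))
  tol <- res$generations$tolerance
  expect_true(all(diff(tol) < 0))
  for (g in unique(res$particles$generation)) {
    w <- res$particles$weight[res$particles$generation == g]
    expect_equal(sum(w), 1)
  }
  # posterior support contained in the prior box
  th <- vapply(res$particles$theta, `[[`, numeric(1), "theta")
  expect_true(all(th >= -10 & th <= 10))
  # posterior interval shrinks relative to the prior
  final <- tidy(res)
  expect_lt(diff(range(final$theta)), 20)
})

test_that("identical seeds reproduce a run exactly", {
  model <- list(m = list(
    prior = uni_prior(),
    distance = function(th) abs(mean(rnorm(10, th[["theta"]], 1)))
  ))
  cfg <- smc_config(n_particles = 60, max_generations = 3, seed = 21)
  r1 <- abc_smc(model, cfg)
  r2 <- abc_smc(model, cfg)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("a superfluous-parameter model loses to the generating model", {
  # data from N(2, 1); model A has the right structure, model B carries an
  # extra useless parameter that only dilutes its prior mass
  set.seed(9)
  obs_mean <- mean(rnorm(25, 2, 1))
  mkdist <- function(extra) {
    function(th) {
      abs(mean(rnorm(25, th[["theta"]], 1)) - obs_mean) +
        if (extra) 0 * th[["junk"]] else 0
    }
  }
  models <- list(
    A = list(prior = uni_prior(), distance = mkdist(FALSE)),
    B = list(prior = prior_spec(data.frame(
      parameter = c("theta", "junk"), dist = "uniform",
      lower = c(-10, -10), upper = c(10, 10))), distance = mkdist(TRUE))
  )
  wins <- vapply(1:6, function(s) {
    res <- abc_smc(models, smc_config(n_particles = 120, max_generations = 4,
                                      seed = 100 + s))
    f <- res$model_frequencies
    f$model[which.max(f$count)]
  }, character(1))
  expect_gte(sum(wins == "A"), 4)
})
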