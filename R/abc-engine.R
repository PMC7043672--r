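#' Configuration of an ABC-SMC run
#'
#' @param n_particles Particles per generation (>= 2).
#' @param alpha Tolerance-schedule quantile in (0, 1): each generation's
#'   tolerance is the `alpha`-quantile of the previous generation's accepted
#'   distances (generation 1 uses a pilot sample from the prior).
#' @param max_generations Number of SMC generations after the pilot.
#' @param min_acceptance Stop early when a generation's acceptance rate
#'   falls below this floor.
#' @param eps_init Optional fixed initial tolerance (default: pilot
#'   `alpha`-quantile). `Inf` accepts everything in generation 1.
#' @param kernel_factor Perturbation-kernel scale as a multiple of the
#'   previous generation's per-parameter spread (range), default 0.5.
#' @param max_tries_factor Proposal budget per generation, as a multiple of
#'   `n_particles`; exhausting it is reported as an error together with the
#'   generation's tolerance.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A list of class `copred_smc_config`.
#' @export
smc_config <- function(n_particles = 1000, alpha = 0.5, max_generations = 8,
                       min_acceptance = 0.005, eps_init = NULL,
                       kernel_factor = 0.5, max_tries_factor = 500,
                       seed = 1L) {
  if (n_particles < 2) abort("`n_particles` must be >= 2.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  structure(list(n_particles = as.integer(n_particles), alpha = alpha,
                 max_generations = as.integer(max_generations),
                 min_acceptance = min_acceptance, eps_init = eps_init,
                 kernel_factor = kernel_factor,
                 max_tries_factor = max_tries_factor, seed = as.integer(seed)),
            class = "copred_smc_config")
}

# ---- prior helpers ---------------------------------------------------------

# transformed representation: log10 space for loguniform, raw for uniform
prior_info <- function(prior) {
  b <- prior$bounds
  islog <- b$dist == "loguniform"
  lo <- ifelse(islog, log10(b$lower), b$lower)
  hi <- ifelse(islog, log10(b$upper), b$upper)
  list(names = b$parameter, islog = islog, lower = lo, upper = hi,
       log_dens = -sum(log(hi - lo)))
}

to_trans <- function(theta, info) {
  x <- theta[info$names]
  ifelse(info$islog, log10(x), x)
}

to_natural <- function(x, info) {
  setNames(ifelse(info$islog, 10^x, x), info$names)
}

#' Draw parameter vectors (and optionally model indices) from the prior
#'
#' Log-uniform parameters are drawn uniformly on the log10 scale, uniform
#' parameters on the natural scale. With several models, the model index is
#' uniform over them and parameters are drawn from that model's prior.
#'
#' @param prior A `copred_prior`, or a named list of them (one per model).
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return A tibble with a `model` column (if several models) and one row per
#'   draw; parameter values are in a `theta` list-column of named vectors.
#' @export
sample_prior <- function(prior, n = 1, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  priors <- if (inherits(prior, "copred_prior")) list(model = prior) else prior
  stopifnot(all(vapply(priors, inherits, TRUE, "copred_prior")))
  models <- names(priors)
  idx <- if (length(priors) == 1L) rep(1L, n) else sample.int(length(priors), n, replace = TRUE)
  theta <- purrr::map(idx, function(i) {
    info <- prior_info(priors[[i]])
    to_natural(runif(length(info$lower), info$lower, info$upper), info)
  })
  out <- tibble(model = models[idx], theta = theta)
  if (length(priors) == 1L && inherits(prior, "copred_prior")) out$model <- NULL
  out
}

#' Perturb a particle with a componentwise Gaussian kernel
#'
#' Perturbation happens in the prior's transformed space (log10 for
#' log-uniform parameters). Proposals falling outside the prior support are
#' redrawn; a zero kernel scale returns the particle unchanged.
#'
#' @param theta Named parameter vector (natural scale).
#' @param prior The `copred_prior` defining support and transforms.
#' @param scales Named vector of kernel standard deviations in transformed
#'   space, e.g. from [kernel_scales()].
#' @param max_tries Redraw budget before giving up and returning `theta`.
#' @return A named parameter vector within the prior support.
#' @export
perturb_particle <- function(theta, prior, scales, max_tries = 1000) {
  info <- prior_info(prior)
  x <- to_trans(theta, info)
  s <- scales[info$names]
  s[is.na(s)] <- 0
  if (all(s == 0)) return(to_natural(x, info))
  for (i in seq_len(max_tries)) {
    prop <- x + rnorm(length(x), 0, s)
    if (all(prop >= info$lower & prop <= info$upper)) {
      return(to_natural(prop, info))
    }
  }
  to_natural(x, info)
}

#' Kernel scales from a cloud of accepted particles
#'
#' The per-parameter scale is `factor` times the spread (range) of the cloud
#' in transformed space.
#'
#' @param cloud Matrix of particles in transformed space (rows = particles).
#' @param factor Multiple of the spread, default 0.5.
#' @return Named numeric vector of standard deviations.
#' @export
kernel_scales <- function(cloud, factor = 0.5) {
  rng <- apply(cloud, 2, function(v) diff(range(v)))
  setNames(factor * rng, colnames(cloud))
}

# ---- the SMC engine --------------------------------------------------------

#' Run ABC-SMC over a set of candidate models
#'
#' Generic likelihood-free engine: each model supplies a prior and a distance
#' function mapping a named parameter vector to a non-negative distance
#' between simulated and observed data. The model index is part of the
#' sampled space (uniform model prior); generation 1 is rejection sampling
#' from the prior at the initial tolerance (the `alpha`-quantile of a pilot
#' sample), later generations resample-perturb-reweight with standard
#' importance weights and a quantile tolerance schedule. Models with no
#' surviving particles drop out of the proposal mixture.
#'
#' @param models Named list; each element a list with components `prior`
#'   (a `copred_prior`) and `distance` (function of a named parameter
#'   vector). Failed simulations should return `Inf`.
#' @param config A `copred_smc_config`.
#' @return A `copred_smc` object; see [tidy.copred_smc()] and
#'   [glance.copred_smc()].
#' @export
abc_smc <- function(models, config = smc_config()) {
  stopifnot(is.list(models), length(models) >= 1, !is.null(names(models)))
  infos <- purrr::map(models, function(m) prior_info(m$prior))
  n <- config$n_particles
  n_models <- length(models)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  draw_prior <- function(mi) {
    info <- infos[[mi]]
    runif(length(info$lower), info$lower, info$upper)
  }
  eval_dist <- function(mi, x_trans) {
    theta <- to_natural(x_trans, infos[[mi]])
    d <- models[[mi]]$distance(theta)
    if (!is.finite(d) || d < 0) Inf else d
  }

  # pilot sample sets the initial tolerance
  if (is.null(config$eps_init)) {
    pilot <- vapply(seq_len(n), function(i) {
      mi <- sample.int(n_models, 1)
      eval_dist(mi, draw_prior(mi))
    }, numeric(1))
    finite <- pilot[is.finite(pilot)]
    if (!length(finite)) abort("All pilot simulations failed.")
    eps <- unname(quantile(finite, config$alpha))
  } else {
    eps <- config$eps_init
  }

  # per-generation state: list per model of (matrix x, weights w), plus d
  gen_log <- list()
  particles_log <- list()
  prev <- NULL
  alive <- seq_len(n_models)

  for (t in seq_len(config$max_generations)) {
    if (t > 1) {
      d_prev <- unlist(purrr::map(prev, "d"))
      eps_new <- unname(quantile(d_prev, config$alpha))
      eps <- min(eps_new, eps * (1 - 1e-12))
    }
    scales <- purrr::map(alive, function(mi) {
      if (is.null(prev) || is.null(prev[[as.character(mi)]])) return(NULL)
      kernel_scales(prev[[as.character(mi)]]$x, config$kernel_factor)
    })
    names(scales) <- as.character(alive)

    acc_m <- integer(0); acc_x <- list(); acc_d <- numeric(0)
    tries <- 0L
    max_tries <- config$max_tries_factor * n
    while (length(acc_m) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf(
          "ABC-SMC generation %d: proposal budget exhausted at tolerance %.6g (%d/%d accepted).",
          t, eps, length(acc_m), n))
      }
      mi <- alive[[sample.int(length(alive), 1)]]
      if (t == 1) {
        x <- draw_prior(mi)
      } else {
        src <- prev[[as.character(mi)]]
        j <- sample.int(nrow(src$x), 1, prob = src$w)
        x <- perturb_trans(src$x[j, ], infos[[mi]], scales[[as.character(mi)]])
      }
      d <- eval_dist(mi, x)
      if (d <= eps) {
        acc_m <- c(acc_m, mi)
        acc_x[[length(acc_x) + 1L]] <- x
        acc_d <- c(acc_d, d)
      }
    }
    rate <- n / tries

    # importance weights (natural-log scale, normalized globally)
    logw <- numeric(n)
    if (t == 1) {
      logw[] <- 0
    } else {
      n_alive <- length(alive)
      for (mi in unique(acc_m)) {
        src <- prev[[as.character(mi)]]
        s <- scales[[as.character(mi)]]
        pos <- s > 0
        sel <- which(acc_m == mi)
        for (i in sel) {
          x <- acc_x[[i]]
          if (any(pos)) {
            lk <- vapply(seq_len(nrow(src$x)), function(j) {
              sum(dnorm(x[pos], src$x[j, pos], s[pos], log = TRUE))
            }, numeric(1))
            mix <- log(sum(src$w * exp(lk - max(lk)))) + max(lk)
          } else {
            mix <- 0
          }
          logw[i] <- infos[[mi]]$log_dens - (log(1 / n_alive) + mix)
        }
      }
    }
    w <- exp(logw - max(logw))
    w <- w / sum(w)

    gen_log[[t]] <- tibble(generation = t, tolerance = eps,
                           n_accepted = n, tries = tries,
                           acceptance_rate = rate)
    particles_log[[t]] <- tibble(
      generation = t,
      model = names(models)[acc_m],
      weight = w,
      distance = acc_d,
      theta = purrr::map2(acc_m, acc_x, function(mi, x) to_natural(x, infos[[mi]]))
    )

    prev <- list()
    for (mi in unique(acc_m)) {
      sel <- which(acc_m == mi)
      prev[[as.character(mi)]] <- list(
        x = do.call(rbind, acc_x[sel]),
        w = w[sel] / sum(w[sel]),
        d = acc_d[sel]
      )
    }
    colnames_set <- function(mi) {
      colnames(prev[[as.character(mi)]]$x) <<- infos[[mi]]$names
    }
    purrr::walk(unique(acc_m), colnames_set)
    alive <- sort(unique(acc_m))

    if (rate < config$min_acceptance) break
  }

  final <- particles_log[[length(particles_log)]]
  freq <- dplyr::count(final, .data$model, name = "count")
  freq$frequency <- freq$count / sum(freq$count)

  structure(list(
    models = names(models),
    priors = purrr::map(models, "prior"),
    config = config,
    generations = dplyr::bind_rows(gen_log),
    particles = dplyr::bind_rows(particles_log),
    model_frequencies = freq
  ), class = "copred_smc")
}

# perturb in transformed space (internal fast path of perturb_particle)
perturb_trans <- function(x, info, scales, max_tries = 1000) {
  s <- scales[info$names]
  s[is.na(s)] <- 0
  if (all(s == 0)) return(x)
  for (i in seq_len(max_tries)) {
    prop <- x + rnorm(length(x), 0, s)
    if (all(prop >= info$lower & prop <= info$upper)) return(prop)
  }
  x
}

#' @export
print.copred_smc <- function(x, ...) {
  cat("<copred_smc> ", length(x$models), " model(s), ",
      nrow(x$generations), " generation(s)\n", sep = "")
  print(x$generations)
  cat("Final-generation model frequencies:\n")
  print(x$model_frequencies)
  invisible(x)
}

#' Tidy the accepted particles of an ABC-SMC run
#'
#' @param x A `copred_smc`.
#' @param generation Generations to keep (default: final).
#' @param ... Unused.
#' @return A tibble with one row per particle and one column per parameter.
#' @export
tidy.copred_smc <- function(x, generation = max(x$particles$generation), ...) {
  p <- x$particles[x$particles$generation %in% generation, ]
  wide <- dplyr::bind_rows(purrr::map(p$theta, function(v) as_tibble(as.list(v))))
  dplyr::bind_cols(p[c("generation", "model", "weight", "distance")], wide)
}

#' One-row summary of an ABC-SMC run
#'
#' @param x A `copred_smc`.
#' @param ... Unused.
#' @return A tibble with the number of generations, the final tolerance and
#'   acceptance rate, and the winning model.
#' @export
glance.copred_smc <- function(x, ...) {
  g <- x$generations[nrow(x$generations), ]
  top <- x$model_frequencies[which.max(x$model_frequencies$count), ]
  tibble(n_generations = g$generation, final_tolerance = g$tolerance,
         final_acceptance_rate = g$acceptance_rate,
         winner = top$model, winner_frequency = top$frequency)
}
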