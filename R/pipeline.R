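#' Run one model-competition stage
#'
#' Runs `n_runs` independent seeded ABC-SMC competitions among the candidate
#' variants and reports how often each candidate wins (plurality of
#' final-generation particles).
#'
#' @param candidates Named list of `copred_variant`s (names default to
#'   [variant_label()]).
#' @param obs A `copred_dataset`.
#' @param config A `copred_smc_config`; run `r` uses seed
#'   `config$seed + r`.
#' @param n_runs Number of independent competitions.
#' @param ... Passed to [run_abc_smc()].
#' @return A tibble (class `copred_stage`) with columns `candidate`, `wins`,
#'   `runs`, `win_frequency`, ordered as the candidates; the individual
#'   `copred_smc` results are attached as attribute `"results"`.
#' @export
run_stage <- function(candidates, obs, config = smc_config(), n_runs = 10,
                      ...) {
  if (inherits(candidates, "copred_variant")) candidates <- list(candidates)
  stopifnot(length(candidates) >= 1)
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- vapply(candidates, variant_label, character(1))
  }
  results <- purrr::map(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    run_abc_smc(candidates, obs, config = cfg, ...)
  })
  winners <- vapply(results, function(res) {
    f <- res$model_frequencies
    f$model[which.max(f$count)]
  }, character(1))
  out <- tibble(
    candidate = names(candidates),
    wins = vapply(names(candidates), function(m) sum(winners == m), integer(1),
                  USE.NAMES = FALSE),
    runs = n_runs
  )
  out$win_frequency <- out$wins / out$runs
  structure(out, class = c("copred_stage", class(out)),
            results = results, winners = winners)
}

#' The default hierarchical competition ladder
#'
#' Seven stages mirror the hierarchical selection the model family is built
#' for: (A) number of prey phenotypes; (B) conversion mechanisms between
#' sensitive and plastic-resistant prey; (C) the combined
#' signal-plus-growth-coupled conversion against its parents; (D) the source
#' of the conversion signal; (E) the origin of phage resistance;
#' (F) attack-rate saturation; (G) fixed versus fitted Bdellovibrio
#' mortality. Winner propagation is configuration: each stage's non-competing
#' settings are pinned to the reference ladder's winners.
#'
#' @return Named list of stages; each stage is a named list of
#'   `copred_variant` candidates.
#' @export
default_stage_plan <- function() {
  v <- function(...) model_variant(...)
  list(
    A = list(
      N1 = v("N1"),
      N2 = v("N2", resistance_origin = "both"),
      N3 = v("N3", conversion = "SG", signal_source = "B_only"),
      N4 = v("N4", conversion = "SG", signal_source = "B_only")
    ),
    B = list(
      I = v("N3", conversion = "I"),
      IG = v("N3", conversion = "IG"),
      S = v("N3", conversion = "S", signal_source = "both")
    ),
    C = list(
      IG = v("N3", conversion = "IG"),
      SG = v("N3", conversion = "SG", signal_source = "both"),
      S = v("N3", conversion = "S", signal_source = "both")
    ),
    D = list(
      SBG = v("N3", conversion = "SG", signal_source = "B_only"),
      SG = v("N3", conversion = "SG", signal_source = "both"),
      SVG = v("N3", conversion = "SG", signal_source = "V_only")
    ),
    E = list(
      preexisting = v("N3", conversion = "SG", signal_source = "B_only",
                      resistance_origin = "preexisting"),
      de_novo = v("N3", conversion = "SG", signal_source = "B_only",
                  resistance_origin = "de_novo"),
      both = v("N3", conversion = "SG", signal_source = "B_only",
               resistance_origin = "both")
    ),
    F = list(
      `Pi-Vi` = v("N3", conversion = "SG", signal_source = "B_only",
                  p_saturation = "Pi", v_saturation = "Vi"),
      `Pii-Vi` = v("N3", conversion = "SG", signal_source = "B_only",
                   p_saturation = "Pii", v_saturation = "Vi"),
      `Pi-Vii` = v("N3", conversion = "SG", signal_source = "B_only",
                   p_saturation = "Pi", v_saturation = "Vii"),
      `Pii-Vii` = v("N3", conversion = "SG", signal_source = "B_only",
                    p_saturation = "Pii", v_saturation = "Vii")
    ),
    G = list(
      literature_fixed = v("N3", conversion = "SG", signal_source = "B_only",
                           mortality_mode = "literature_fixed"),
      fitted = v("N3", conversion = "SG", signal_source = "B_only",
                 mortality_mode = "fitted")
    )
  )
}

#' Run a ladder of competition stages
#'
#' @param plan A stage plan as from [default_stage_plan()] (possibly a
#'   subset of stages).
#' @param obs A `copred_dataset`.
#' @param config A `copred_smc_config`.
#' @param n_runs Competitions per stage.
#' @param ... Passed to [run_stage()].
#' @return A tibble with columns `stage`, `candidate`, `wins`, `runs`,
#'   `win_frequency`.
#' @export
run_stage_plan <- function(plan, obs, config = smc_config(), n_runs = 10,
                           ...) {
  purrr::imap_dfr(plan, function(cands, stage) {
    res <- run_stage(cands, obs, config = config, n_runs = n_runs, ...)
    dplyr::mutate(as_tibble(res), stage = stage, .before = 1)
  })
}

#' Typical parameter set of a fitted model (PCA medoid)
#'
#' Standardises the final-generation particles in the prior's transformed
#' space (log10 for log-uniform parameters), rotates them by principal
#' component analysis, and returns the accepted particle - never a synthetic
#' average - closest to the weighted centroid, with per-component distances
#' weighted by each component's share of variance. Being a real accepted
#' particle, the result is always simulable.
#'
#' @param result A `copred_smc` from [run_abc_smc()] or [fit_final()].
#' @param model Model name to summarise (default: plurality winner).
#' @return A `copred_params` (full parameter set, pinned values merged in),
#'   with the winning particle's index as attribute `"particle"`.
#' @export
typical_parameter_set <- function(result, model = NULL) {
  stopifnot(inherits(result, "copred_smc"))
  final <- result$particles[result$particles$generation ==
                              max(result$particles$generation), ]
  if (!nrow(final)) abort("No accepted particles.")
  model <- model %||%
    result$model_frequencies$model[which.max(result$model_frequencies$count)]
  sel <- final[final$model == model, ]
  if (!nrow(sel)) abort(paste0("No particles for model ", model, "."))
  prior <- result$priors[[model]]
  info <- prior_info(prior)

  X <- do.call(rbind, purrr::map(sel$theta, to_trans, info = info))
  colnames(X) <- info$names
  w <- sel$weight / sum(sel$weight)
  idx <- if (nrow(X) == 1L) {
    1L
  } else {
    mu <- colSums(X * w)
    sdv <- sqrt(colSums(w * sweep(X, 2, mu)^2))
    keep <- sdv > 0
    if (!any(keep)) {
      1L
    } else {
      Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
      pca <- prcomp(Xs, center = FALSE, scale. = FALSE)
      scores <- pca$x
      centroid <- colSums(scores * w)
      share <- pca$sdev^2 / sum(pca$sdev^2)
      d2 <- colSums(share * (t(scores) - centroid)^2)
      which.min(d2)
    }
  }
  theta <- sel$theta[[idx]]
  out <- parameter_set(base = reference_parameters(),
                       c(prior$fixed, as.list(theta)))
  attr(out, "particle") <- idx
  attr(out, "model") <- model
  out
}

#' Initial-density sweep
#'
#' Re-simulates every condition of the design with the initial density of
#' one population at a time scaled by 0.1, 1 and 10, and classifies prey
#' survival (total prey at the end of the experiment at or above the
#' detection limit).
#'
#' @param variant A `copred_variant`.
#' @param params A `copred_params` (e.g. a typical parameter set).
#' @param design A `copred_design`.
#' @param factors Scaling factors (default `c(0.1, 1, 10)`).
#' @param solver_opts Passed to [simulate_predation()].
#' @return A tibble (class `copred_sweep`) with columns `population`
#'   (whose initial density was scaled), `factor`, `condition`, the
#'   end-state observable densities, and `prey_survival`.
#' @export
density_sweep <- function(variant, params, design = experiment_design(),
                          factors = c(0.1, 1, 10), solver_opts = list()) {
  stopifnot(inherits(design, "copred_design"))
  params <- parameter_set(base = params, N0 = design$N0, P0 = design$P0,
                          V0 = design$V0)
  times <- seq(0, design$duration, by = design$sampling_interval)
  grid <- tidyr::expand_grid(
    population = c("prey", "bdellovibrio", "phage"),
    factor = factors,
    condition = design$conditions
  )
  rows <- purrr::pmap(grid, function(population, factor, condition) {
    p2 <- switch(population,
                 prey = parameter_set(base = params, N0 = params$N0 * factor),
                 bdellovibrio = parameter_set(base = params, P0 = params$P0 * factor),
                 phage = parameter_set(base = params, V0 = params$V0 * factor))
    traj <- simulate_predation(variant, p2, times = times,
                               condition = condition,
                               solver_opts = solver_opts)
    endo <- observables(traj)[length(times), ]
    tibble(population = population, factor = factor, condition = condition,
           prey_end = endo$prey, bdellovibrio_end = endo$bdellovibrio,
           phage_end = endo$phage,
           prey_survival = endo$prey >= design$detection_limit)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("copred_sweep", class(out)),
            variant = variant, design = design)
}
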