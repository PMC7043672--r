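# fast distance closure for one variant against a fixed dataset:
# precomputes the observed log10 summary matrices and calls the compiled
# right-hand side directly, returning Inf on any integration failure.
make_variant_distance <- function(variant, prior, obs,
                                  solver_opts = list()) {
  opts <- modifyList(list(rtol = 1e-6, atol = 1e-4, maxsteps = 1e5,
                          method = "lsoda"), solver_opts)
  limit <- attr(obs, "design")$detection_limit %||% 10
  conds <- unique(obs$condition)
  times <- sort(unique(obs$time_h))
  nt <- length(times)
  pops <- c("prey", "bdellovibrio", "phage")

  obs_sum <- summarise_log10(obs, limit)
  obs_mats <- purrr::map(conds, function(cond) {
    s <- obs_sum[obs_sum$condition == cond, ]
    m <- matrix(NA_real_, nt, 3, dimnames = list(NULL, pops))
    for (p in pops) {
      sp <- s[s$population == p, ]
      m[match(sp$time_h, times), p] <- sp$log10_density
    }
    if (anyNA(m)) abort("Observed dataset has an incomplete grid.")
    m
  })
  names(obs_mats) <- conds

  flags <- variant_flags(variant)
  template <- unlist(reference_parameters())
  template[names(prior$fixed)] <- unlist(prior$fixed)
  preexisting <- !is.null(variant$resistance_origin) &&
    variant$resistance_origin %in% c("preexisting", "both") &&
    variant$prey_types %in% c("N2", "N3", "N4")
  has_p <- c(prey_only = FALSE, bdellovibrio_only = TRUE,
             phage_only = FALSE, dual = TRUE)
  has_v <- c(prey_only = FALSE, bdellovibrio_only = FALSE,
             phage_only = TRUE, dual = TRUE)

  function(theta) {
    pv <- template
    pv[names(theta)] <- theta
    pvec <- c(pv[.copred_par_names[1:18]], flags)
    total <- 0
    for (cond in conds) {
      init <- numeric(10)
      if (preexisting) {
        init[1] <- (1 - pv[["f_R"]]) * pv[["N0"]]
        init[3] <- pv[["f_R"]] * pv[["N0"]]
      } else {
        init[1] <- pv[["N0"]]
      }
      init[9] <- pv[["M0"]]
      if (has_p[[cond]]) init[5] <- pv[["P0"]]
      if (has_v[[cond]]) init[7] <- pv[["V0"]]

      out <- tryCatch(
        suppressWarnings(deSolve::ode(
          y = init, times = times, func = "copred_derivs", parms = pvec,
          dllname = "copred", initfunc = "copred_init", method = opts$method,
          rtol = opts$rtol, atol = opts$atol, maxsteps = opts$maxsteps
        )),
        error = function(e) NULL
      )
      if (is.null(out) || nrow(out) < nt) return(Inf)
      istate <- attr(out, "istate")
      if (!is.null(istate) && istate[1] < 0) return(Inf)
      if (any(!is.finite(out[, -1]))) return(Inf)
      prey <- pmax(out[, 2], 0) + pmax(out[, 3], 0) + pmax(out[, 4], 0) + pmax(out[, 5], 0)
      bdel <- pmax(out[, 6], 0) + pmax(out[, 7], 0)
      phage <- pmax(out[, 8], 0) + pmax(out[, 9], 0)
      sim <- log10(pmax(cbind(prey, bdel, phage), limit))
      total <- total + sum((sim - obs_mats[[cond]])^2)
    }
    total
  }
}

#' Joint model selection and parameter inference by ABC-SMC
#'
#' Fits one or more model variants to an observed (or synthetic) dataset.
#' The particle space is the pair (model index, parameter vector): the model
#' index has a uniform prior and each variant carries its own parameter
#' prior. A competition "win" is a plurality of final-generation particles.
#'
#' @param models A `copred_variant` or list of them. Names default to
#'   [variant_label()].
#' @param obs A `copred_dataset`.
#' @param config A `copred_smc_config`.
#' @param priors Optional named list of `copred_prior` objects, one per
#'   model; defaults to [default_priors()] for each variant.
#' @param solver_opts ODE solver options for the fitting simulations
#'   (defaults are looser than [simulate_predation()]'s: `rtol = 1e-6`).
#' @return A `copred_smc` (see [abc_smc()]) with the variants attached.
#' @export
run_abc_smc <- function(models, obs, config = smc_config(), priors = NULL,
                        solver_opts = list()) {
  if (inherits(models, "copred_variant")) models <- list(models)
  stopifnot(all(vapply(models, inherits, TRUE, "copred_variant")))
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- vapply(models, variant_label, character(1))
  }
  priors <- priors %||% purrr::map(models, default_priors)
  engine_models <- purrr::map2(models, priors, function(v, pr) {
    list(prior = pr, distance = make_variant_distance(v, pr, obs, solver_opts))
  })
  res <- abc_smc(engine_models, config)
  res$variants <- models
  res
}

#' Fit the final model variant, optionally withholding dual predation
#'
#' With `data_subset = "exclude_dual"` the dual-predation condition
#' contributes nothing to the distance, so the fit uses only the prey-only
#' and single-predator conditions; simulating the fitted model under the
#' dual condition then yields an out-of-sample prediction.
#'
#' @param variant A `copred_variant`.
#' @param obs A `copred_dataset`.
#' @param config A `copred_smc_config`.
#' @param data_subset `"all"` or `"exclude_dual"`.
#' @param ... Passed to [run_abc_smc()].
#' @return A `copred_smc`.
#' @export
fit_final <- function(variant, obs, config = smc_config(),
                      data_subset = c("all", "exclude_dual"), ...) {
  data_subset <- match.arg(data_subset)
  if (data_subset == "exclude_dual") {
    keep <- obs$condition != "dual"
    obs <- new_copred_dataset(obs[keep, , drop = FALSE],
                              design = attr(obs, "design"),
                              noise = attr(obs, "noise"),
                              variant = attr(obs, "variant"),
                              params = attr(obs, "params"))
  }
  if (!nrow(obs)) abort("No conditions left to fit after subsetting.")
  run_abc_smc(list(variant), obs, config = config, ...)
}
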