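#' Experimental design of a predation-kinetics experiment
#'
#' Defaults emulate the 48-h experiments the models are fitted to: four
#' culture conditions sampled every 2 h in triplicate, plating detection
#' limit of 10 CFU/ml, and mean initial densities of 2.9e8 CFU/ml prey,
#' 2.8e6 PFU/ml Bdellovibrio and 3.7e6 PFU/ml phage.
#'
#' @param duration Experiment length (h).
#' @param sampling_interval Sampling interval (h); must divide `duration`.
#' @param replicates Technical replicates per sample point.
#' @param conditions Subset of `"prey_only"`, `"bdellovibrio_only"`,
#'   `"phage_only"`, `"dual"`.
#' @param detection_limit Smallest countable density (per ml).
#' @param N0,P0,V0 Initial densities (per ml) written into the generating
#'   parameter set.
#' @return A list of class `copred_design`.
#' @export
experiment_design <- function(duration = 48, sampling_interval = 2,
                              replicates = 3,
                              conditions = c("prey_only", "bdellovibrio_only",
                                             "phage_only", "dual"),
                              detection_limit = 10,
                              N0 = 2.9e8, P0 = 2.8e6, V0 = 3.7e6) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (duration <= 0) abort("`duration` must be positive.")
  if (sampling_interval <= 0 ||
      abs(duration / sampling_interval - round(duration / sampling_interval)) > 1e-9) {
    abort("`sampling_interval` must be positive and divide `duration`.")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (detection_limit < 0) abort("`detection_limit` must be >= 0.")
  structure(list(duration = duration, sampling_interval = sampling_interval,
                 replicates = as.integer(replicates), conditions = conditions,
                 detection_limit = detection_limit, N0 = N0, P0 = P0, V0 = V0),
            class = "copred_design")
}

#' Replicate-noise model for synthetic plate counts
#'
#' Counts are perturbed multiplicatively: each replicate is the true density
#' times `10^e` with `e ~ Normal(0, log10_sd)`, reflecting dilution and
#' pipetting error dominating plated counts at these densities. Optionally,
#' counts below 100/ml can instead be drawn from a Poisson distribution
#' around the noisy density (off by default).
#'
#' @param log10_sd Replicate standard deviation on the log10 scale.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param poisson_counts If `TRUE`, re-draw densities below 100/ml as Poisson.
#' @return A list of class `copred_noise`.
#' @export
noise_model <- function(log10_sd = 0.15, seed = 1L, poisson_counts = FALSE) {
  if (log10_sd < 0) abort("`log10_sd` must be >= 0.")
  structure(list(log10_sd = log10_sd, seed = as.integer(seed),
                 poisson_counts = isTRUE(poisson_counts)),
            class = "copred_noise")
}

#' Generate a synthetic predation-kinetics dataset
#'
#' Simulates the model for every condition in the design, maps trajectories
#' to plate-count observables, applies multiplicative replicate noise, and
#' censors values below the detection limit (stored as `NA` with
#' `censored = TRUE`, never as zeros).
#'
#' @param variant Generating `copred_variant`.
#' @param params Generating `copred_params`; its `N0`, `P0`, `V0` are
#'   overridden by the design's initial densities.
#' @param design A `copred_design`.
#' @param noise A `copred_noise`.
#' @param solver_opts Passed to [simulate_predation()].
#' @return A tibble of class `copred_dataset` with columns `condition`,
#'   `population`, `time_h`, `replicate`, `density_per_ml`, `censored`,
#'   carrying design, noise and generating model as attributes.
#' @examples
#' d <- generate_dataset(design = experiment_design(conditions = "dual"),
#'                       noise = noise_model(seed = 7))
#' dplyr::count(d, condition, population)
#' @export
generate_dataset <- function(variant = reference_variant(),
                             params = reference_parameters(),
                             design = experiment_design(),
                             noise = noise_model(),
                             solver_opts = list()) {
  stopifnot(inherits(design, "copred_design"), inherits(noise, "copred_noise"))
  params <- parameter_set(base = params, N0 = design$N0, P0 = design$P0,
                          V0 = design$V0)
  times <- seq(0, design$duration, by = design$sampling_interval)
  pops <- c("prey", "bdellovibrio", "phage")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(noise$seed)

  rows <- purrr::map(design$conditions, function(cond) {
    traj <- tryCatch(
      simulate_predation(variant, params, times = times, condition = cond,
                         solver_opts = solver_opts),
      copred_integration_error = function(e) {
        abort(paste0("Simulation failed for condition '", cond, "': ",
                     conditionMessage(e)), class = "copred_integration_error")
      }
    )
    obs <- observables(traj)
    truth <- tidyr::pivot_longer(obs, -"time_h", names_to = "population",
                                 values_to = "truth")
    truth$population <- factor(truth$population, levels = pops)
    truth <- dplyr::arrange(truth, .data$population, .data$time_h)
    reps <- tidyr::expand_grid(truth, replicate = seq_len(design$replicates))
    eps <- rnorm(nrow(reps), mean = 0, sd = noise$log10_sd)
    value <- reps$truth * 10^eps
    if (noise$poisson_counts) {
      low <- which(value < 100)
      if (length(low)) value[low] <- rpois(length(low), value[low])
    }
    censored <- value < design$detection_limit
    tibble(
      condition = cond,
      population = as.character(reps$population),
      time_h = reps$time_h,
      replicate = reps$replicate,
      density_per_ml = ifelse(censored, NA_real_, value),
      censored = censored
    )
  })
  out <- dplyr::bind_rows(rows)
  new_copred_dataset(out, design = design, noise = noise,
                     variant = variant, params = params)
}

new_copred_dataset <- function(x, design, noise = NULL, variant = NULL,
                               params = NULL) {
  structure(as_tibble(x),
            class = c("copred_dataset", class(as_tibble(x))),
            design = design, noise = noise, variant = variant, params = params)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
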