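#' Distance between simulated observables and an observed dataset
#'
#' Both sides are reduced to log10 densities floored at the detection limit;
#' observed replicates are first averaged on the log10 scale with censored
#' replicates entered at the detection limit. The distance is the sum of
#' squared differences over every condition x population x time point the
#' two sides share (they must share all of them).
#'
#' @param sim Simulated series: a data frame with columns `condition`,
#'   `population`, `time_h`, `density_per_ml` (no replicates, noiseless), as
#'   produced by [simulated_series()].
#' @param obs A `copred_dataset` (or data frame with the dataset columns).
#' @param detection_limit Flooring level; defaults to the dataset design's.
#' @return A non-negative number.
#' @examples
#' d <- generate_dataset(design = experiment_design(conditions = "dual"))
#' s <- simulated_series(reference_variant(), reference_parameters(), d)
#' dataset_distance(s, d)
#' @export
dataset_distance <- function(sim, obs, detection_limit = NULL) {
  limit <- detection_limit %||% attr(obs, "design")$detection_limit %||% 10
  obs_sum <- summarise_log10(obs, limit)
  sim_sum <- summarise_log10(sim, limit)
  key_obs <- paste(obs_sum$condition, obs_sum$population, obs_sum$time_h)
  key_sim <- paste(sim_sum$condition, sim_sum$population, sim_sum$time_h)
  if (length(key_obs) != length(key_sim) || !setequal(key_obs, key_sim)) {
    abort("Simulated and observed series do not share the same grid.")
  }
  sum((sim_sum$log10_density[match(key_obs, key_sim)] - obs_sum$log10_density)^2)
}

# log10 replicate means with censored values entered at the detection limit
summarise_log10 <- function(x, limit) {
  x <- as_tibble(x)
  stopifnot(all(c("condition", "population", "time_h", "density_per_ml") %in% names(x)))
  floor_at <- max(limit, .Machine$double.xmin)
  val <- x$density_per_ml
  if ("censored" %in% names(x)) val[which(x$censored)] <- limit
  if (anyNA(val)) abort("Missing densities that are not flagged censored.")
  x$log10_density <- log10(pmax(val, floor_at))
  dplyr::summarise(x, log10_density = mean(.data$log10_density),
                   .by = c("condition", "population", "time_h"))
}

#' Noiseless simulated counterpart of a dataset
#'
#' Simulates `variant` under `params` on the dataset's design grid for every
#' condition present and returns the observable series in the dataset's tidy
#' layout (one noiseless value per condition x population x time).
#'
#' @param variant A `copred_variant`.
#' @param params A `copred_params`.
#' @param obs A `copred_dataset` supplying conditions and time grid.
#' @param solver_opts Passed to [simulate_predation()].
#' @return A tibble with columns `condition`, `population`, `time_h`,
#'   `density_per_ml`.
#' @export
simulated_series <- function(variant, params, obs, solver_opts = list()) {
  conds <- unique(obs$condition)
  times <- sort(unique(obs$time_h))
  purrr::map_dfr(conds, function(cond) {
    traj <- simulate_predation(variant, params, times = times,
                               condition = cond, solver_opts = solver_opts)
    o <- observables(traj)
    tidyr::pivot_longer(o, -"time_h", names_to = "population",
                        values_to = "density_per_ml") |>
      dplyr::mutate(condition = cond, .before = 1)
  })
}
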