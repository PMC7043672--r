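.copred_par_names <- c(
  "mu_max", "K_M", "a_P", "K_P", "a_V", "K_V", "k_B", "beta_P", "k_I",
  "beta_V", "eps_B", "eps_I", "d_P", "sigma_C", "k_sig", "r_I", "r_back",
  "m", "f_R", "N0", "P0", "V0", "M0"
)

#' Build a full parameter set for the dual-predation model
#'
#' Starts from the synthetic reference values (see [reference_parameters()])
#' and overrides any named subset. Units: hours and per-ml densities
#' throughout; the medium `M` is denominated in prey-cell equivalents with
#' unit yield (one equivalent makes one prey cell).
#'
#' Parameters:
#' \describe{
#'   \item{mu_max}{prey maximum specific growth rate (1/h)}
#'   \item{K_M}{medium half-saturation for prey growth (cell-equivalents/ml)}
#'   \item{a_P}{Bdellovibrio attack rate: ml/h under `Pi` (mass action);
#'     maximum per-predator attack rate (1/h) under `Pii`}
#'   \item{K_P}{prey half-saturation of the saturating Bdellovibrio attack
#'     (cells/ml, `Pii` only)}
#'   \item{a_V}{phage adsorption rate: ml/h under `Vi`; 1/h under `Vii`}
#'   \item{K_V}{prey half-saturation of the saturating phage attack
#'     (cells/ml, `Vii` only)}
#'   \item{k_B}{bdelloplast progression-and-lysis rate (1/h)}
#'   \item{beta_P}{Bdellovibrio burst size (progeny per bdelloplast)}
#'   \item{k_I}{infected-cell lysis rate (1/h)}
#'   \item{beta_V}{phage burst size (virions per infected cell)}
#'   \item{eps_B, eps_I}{medium released per bdelloplast / infected-cell lysis
#'     (cell-equivalents, strictly < 1: the residue cannot rebuild a whole cell)}
#'   \item{d_P}{free-Bdellovibrio mortality rate (1/h)}
#'   \item{sigma_C}{signal produced per predation event (signal units)}
#'   \item{k_sig}{signal-driven conversion rate constant (ml/(units h))}
#'   \item{r_I}{intrinsic forward conversion rate `N_S -> N_P` (1/h)}
#'   \item{r_back}{intrinsic back conversion rate `N_P -> N_S` (1/h)}
#'   \item{m}{de novo phage-resistance mutation probability per prey division}
#'   \item{f_R}{preexisting phage-resistant fraction of the initial prey}
#'   \item{N0, P0, V0, M0}{initial total prey, Bdellovibrio, phage and medium
#'     densities (per ml)}
#' }
#'
#' @param ... Named parameter overrides.
#' @param base Optional base parameter set to override instead of the
#'   reference values.
#' @return A named list of class `copred_params`.
#' @examples
#' parameter_set(mu_max = 0.4, f_R = 1e-6)
#' @export
parameter_set <- function(..., base = NULL) {
  base <- base %||% reference_parameters()
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.list(dots[[1]]) || (is.numeric(dots[[1]]) && !is.null(names(dots[[1]]))))) {
    dots <- as.list(dots[[1]])
  }
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == ""))) {
    abort("All parameter overrides must be named.")
  }
  unknown <- setdiff(names(dots), .copred_par_names)
  if (length(unknown)) {
    abort(paste0("Unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p <- modifyList(unclass(base), dots)
  p <- p[.copred_par_names]
  validate_params(p)
  structure(p, class = "copred_params")
}

validate_params <- function(p) {
  vals <- unlist(p[.copred_par_names])
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort("All parameters must be finite and non-missing.")
  }
  if (any(vals < 0)) {
    bad <- names(vals)[vals < 0]
    abort(paste0("Negative parameter(s): ", paste(bad, collapse = ", ")))
  }
  if (p$beta_P < 1 || p$beta_V < 1) abort("Burst sizes beta_P and beta_V must be >= 1.")
  if (p$m > 1) abort("Mutation probability m must lie in [0, 1].")
  if (p$f_R > 1) abort("Preexisting resistant fraction f_R must lie in [0, 1].")
  if (p$eps_B >= 1 || p$eps_I >= 1) {
    abort("eps_B and eps_I must be < 1 cell-equivalent per lysis event.")
  }
  invisible(p)
}

#' @export
print.copred_params <- function(x, ...) {
  cat("<copred_params>\n")
  print(tibble(parameter = names(x), value = unlist(x)), n = Inf)
  invisible(x)
}

#' @export
as_tibble.copred_params <- function(x, ...) {
  tibble(parameter = names(unclass(x)), value = unname(unlist(x)))
}

#' Synthetic reference parameter set
#'
#' A single parameter set, authored for this package, that drives the
#' reference variant (see [reference_variant()]) through the qualitative and
#' quantitative regimes of the 48-h predation-kinetics experiments the
#' synthetic-data generator emulates: prey-only cultures stay viable on a
#' limited medium; phage-only predation crashes prey to roughly 2 x 10^3
#' CFU/ml around 6 h before phage-resistant regrowth restores roughly the
#' starting density; Bdellovibrio-only predation leaves a plastic-resistant
#' plateau around 2 x 10^4 CFU/ml; and dual predation eradicates all prey
#' below the 10 CFU/ml detection limit by 14 h. It is a synthetic stand-in
#' for a fitted "typical" parameter set, not a published fit; the calibration
#' rationale is described in the methods vignette.
#'
#' @return A `copred_params`.
#' @export
reference_parameters <- function() {
  structure(list(
    mu_max = 0.6,      # 1/h, late-log E. coli in spent-medium/buffer mix
    K_M = 1e8,         # cell-equivalents/ml
    a_P = 2.0,         # 1/h under Pii (max per-predator attack rate)
    K_P = 4e7,         # cells/ml; Bdellovibrio saturates at low prey density
    a_V = 5e-10,       # ml/h phage adsorption (Vi, mass action)
    K_V = 1e9,         # unused under Vi
    k_B = 0.25,        # 1/h, ~4 h bdelloplast cycle
    beta_P = 3.5,      # progeny per bdelloplast
    k_I = 0.6,         # 1/h, ~100 min latent-plus-lysis period
    beta_V = 80,       # virions per lysed cell
    eps_B = 0.2,       # cell-equivalents returned per bdelloplast lysis
    eps_I = 0.5,       # cell-equivalents returned per infected-cell lysis
    d_P = 0.03,        # 1/h free-Bdellovibrio mortality (literature scale)
    sigma_C = 1e-8,    # signal units per predation event
    k_sig = 8e-6,      # ml/(units h)
    r_I = 1e-3,        # 1/h (intrinsic-conversion variants only)
    r_back = 1e-2,     # 1/h (intrinsic back-conversion variants only)
    m = 1e-7,          # de novo phage-resistance probability per division
    f_R = 2.6e-6,      # preexisting phage-resistant fraction
    N0 = 2.9e8,        # CFU/ml initial prey
    P0 = 2.8e6,        # PFU/ml initial Bdellovibrio
    V0 = 3.7e6,        # PFU/ml initial phage
    M0 = 2e8           # cell-equivalents/ml initial medium
  ), class = "copred_params")
}

#' Free (fitted) parameters of a model variant
#'
#' Returns the names of the parameters that the ABC-SMC machinery treats as
#' free under a given variant; everything else is pinned. Measured initial
#' densities (`N0`, `P0`, `V0`) are always pinned; the unobserved initial
#' medium `M0` is always free.
#'
#' @param variant A `copred_variant`.
#' @return Character vector of parameter names.
#' @export
free_parameters <- function(variant) {
  stopifnot(inherits(variant, "copred_variant"))
  free <- c("mu_max", "K_M", "a_P", "a_V", "k_B", "beta_P", "k_I", "beta_V",
            "eps_B", "eps_I", "M0")
  if (variant$p_saturation == "Pii") free <- c(free, "K_P")
  if (variant$v_saturation == "Vii") free <- c(free, "K_V")
  if (variant$mortality_mode == "fitted") free <- c(free, "d_P")
  if (!is.null(variant$resistance_origin)) {
    if (variant$resistance_origin %in% c("preexisting", "both")) free <- c(free, "f_R")
    if (variant$resistance_origin %in% c("de_novo", "both")) free <- c(free, "m")
  }
  if (!is.null(variant$conversion)) {
    free <- c(free, switch(variant$conversion,
                           I = c("r_I", "r_back"),
                           IG = "r_I",
                           S = c("k_sig", "sigma_C", "r_back"),
                           SG = c("k_sig", "sigma_C")))
  }
  intersect(.copred_par_names, free)
}

#' Prior specification for ABC-SMC
#'
#' @param bounds A data frame with columns `parameter`, `dist`
#'   (`"loguniform"` or `"uniform"`), `lower`, `upper`.
#' @param fixed Named numeric vector or list of pinned parameters.
#' @return A `copred_prior`.
#' @export
prior_spec <- function(bounds, fixed = NULL) {
  bounds <- as_tibble(bounds)
  stopifnot(all(c("parameter", "dist", "lower", "upper") %in% names(bounds)))
  if (!all(bounds$dist %in% c("loguniform", "uniform"))) {
    abort("`dist` must be 'loguniform' or 'uniform'.")
  }
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper)) ||
      any(bounds$lower >= bounds$upper)) {
    abort("Prior bounds must be finite with lower < upper.")
  }
  if (any(bounds$dist == "loguniform" & bounds$lower <= 0)) {
    abort("Log-uniform priors need strictly positive lower bounds.")
  }
  structure(list(bounds = bounds, fixed = as.list(fixed %||% list())),
            class = "copred_prior")
}

#' @export
print.copred_prior <- function(x, ...) {
  cat("<copred_prior>", nrow(x$bounds), "free,", length(x$fixed), "fixed\n")
  print(x$bounds, n = Inf)
  invisible(x)
}

#' Default priors for a model variant
#'
#' Broad priors, log-uniform for rate constants, yields and fractions
#' (spanning at least four decades around plausible microbiological scales)
#' and uniform for the lysis-residue yields. These are the package's own
#' defaults, recorded here rather than asserted as any published choice.
#' Parameters not free under `variant` (see [free_parameters()]) are pinned
#' at `pin` values.
#'
#' @param variant A `copred_variant`.
#' @param pin Parameter set providing pinned values (default
#'   [reference_parameters()]).
#' @return A `copred_prior`.
#' @export
default_priors <- function(variant, pin = reference_parameters()) {
  all_bounds <- tibble(
    parameter = c("mu_max", "K_M", "a_P", "K_P", "a_V", "K_V", "k_B",
                  "beta_P", "k_I", "beta_V", "eps_B", "eps_I", "d_P",
                  "sigma_C", "k_sig", "r_I", "r_back", "m", "f_R", "M0"),
    dist = c("loguniform", "loguniform", "loguniform", "loguniform",
             "loguniform", "loguniform", "loguniform", "loguniform",
             "loguniform", "loguniform", "uniform", "uniform", "loguniform",
             "loguniform", "loguniform", "loguniform", "loguniform",
             "loguniform", "loguniform", "loguniform"),
    lower = c(0.05, 1e6, NA, 1e5, 1e-10, 1e6, 0.02, 1.2, 0.1, 10,
              0.01, 0.01, 1e-3, 1e-10, 1e-7, 1e-5, 1e-5, 1e-9, 1e-8, 1e7),
    upper = c(2, 1e10, NA, 1e9, 1e-6, 1e10, 2, 20, 6, 1000,
              0.99, 0.99, 0.5, 1e-6, 1e-3, 0.1, 0.1, 1e-4, 1e-3, 1e10)
  )
  # a_P has different meaning (and scale) under the two functional responses
  ap <- if (variant$p_saturation == "Pii") c(0.05, 20) else c(1e-10, 1e-6)
  all_bounds$lower[all_bounds$parameter == "a_P"] <- ap[1]
  all_bounds$upper[all_bounds$parameter == "a_P"] <- ap[2]

  free <- free_parameters(variant)
  bounds <- all_bounds[all_bounds$parameter %in% free, ]
  bounds <- bounds[match(free, bounds$parameter), ]
  fixed <- unclass(pin)[setdiff(.copred_par_names, free)]
  prior_spec(bounds, fixed)
}

# merge a free-parameter draw with the pinned values into a full set
merge_theta <- function(theta, prior) {
  parameter_set(base = reference_parameters(),
                c(as.list(prior$fixed), as.list(theta)))
}
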