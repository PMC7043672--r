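#' Initial state for a culture condition
#'
#' Builds the ten-compartment state vector at time zero. The initial prey
#' population `N0` is split into sensitive and phage-resistant prey according
#' to `f_R` when the variant carries an `N_R` compartment and phage
#' resistance can pre-exist; predators are present according to the
#' condition; the medium starts at `M0`; all intracellular stages and the
#' signal start at zero.
#'
#' @param params A `copred_params`.
#' @param condition One of `"prey_only"`, `"bdellovibrio_only"`,
#'   `"phage_only"`, `"dual"`.
#' @param variant A `copred_variant` (default [reference_variant()]).
#' @return Named numeric vector over [copred_state_names()].
#' @examples
#' initial_state(reference_parameters(), "dual")
#' @export
initial_state <- function(params,
                          condition = c("dual", "prey_only",
                                        "bdellovibrio_only", "phage_only"),
                          variant = reference_variant()) {
  condition <- match.arg(condition)
  validate_params(params)
  state <- setNames(numeric(10), copred_state_names())
  preexisting <- !is.null(variant$resistance_origin) &&
    variant$resistance_origin %in% c("preexisting", "both") &&
    variant$prey_types %in% c("N2", "N3", "N4")
  if (preexisting) {
    state["N_S"] <- (1 - params$f_R) * params$N0
    state["N_R"] <- params$f_R * params$N0
  } else {
    state["N_S"] <- params$N0
  }
  state["M"] <- params$M0
  if (condition %in% c("bdellovibrio_only", "dual")) state["P"] <- params$P0
  if (condition %in% c("phage_only", "dual")) state["V"] <- params$V0
  state
}

#' Instantaneous rates of change of the model compartments
#'
#' Pure-R evaluation of the model right-hand side: prey growth by Monod
#' uptake of medium, Bdellovibrio attack on `N_S`/`N_R` (optionally
#' saturating in total susceptible prey), phage attack on `N_S`/`N_P`,
#' bdelloplast and infected-cell turnover releasing predator progeny and a
#' sub-cell-equivalent medium residue, Bdellovibrio mortality, phenotype
#' conversions and de novo resistance mutation diverting a fraction of the
#' division flux. The integrator itself uses the identical compiled version
#' of these rates; this function is the readable form used for diagnostics
#' and testing.
#'
#' @param variant A `copred_variant`.
#' @param params A `copred_params`.
#' @param state Named numeric state over [copred_state_names()].
#' @return Named numeric vector of d/dt for every compartment.
#' @export
predation_derivatives <- function(variant, params, state) {
  stopifnot(inherits(variant, "copred_variant"))
  validate_params(params)
  state <- check_state(state, variant)
  p <- params

  has_NR <- variant$prey_types %in% c("N2", "N3", "N4")
  has_NP <- variant$prey_types %in% c("N3", "N4")
  has_ND <- variant$prey_types == "N4"
  signal_conv <- isTRUE(variant$conversion %in% c("S", "SG"))
  growth_back <- isTRUE(variant$conversion %in% c("IG", "SG"))
  m_eff <- if (has_NR && isTRUE(variant$resistance_origin %in% c("de_novo", "both"))) p$m else 0

  NS <- state[["N_S"]]; NP <- state[["N_P"]]; NR <- state[["N_R"]]
  ND <- state[["N_D"]]; P <- state[["P"]]; B <- state[["B"]]
  V <- state[["V"]]; I <- state[["I"]]; M <- state[["M"]]; C <- state[["C"]]

  d <- setNames(numeric(10), copred_state_names())

  phi <- if (M > 0) p$mu_max * M / (p$K_M + M) else 0
  g <- phi * c(NS = NS, NP = NP, NR = NR, ND = ND)
  mf_NS <- m_eff * g[["NS"]]
  mf_NP <- if (has_ND) m_eff * g[["NP"]] else 0

  d["N_S"] <- d["N_S"] + g[["NS"]] - mf_NS
  if (has_NR) d["N_R"] <- d["N_R"] + g[["NR"]] + mf_NS
  if (has_NP) {
    if (growth_back) d["N_S"] <- d["N_S"] + g[["NP"]] - mf_NP
    else d["N_P"] <- d["N_P"] + g[["NP"]] - mf_NP
  }
  if (has_ND) {
    d["N_D"] <- d["N_D"] + mf_NP
    if (growth_back) d["N_R"] <- d["N_R"] + g[["ND"]]
    else d["N_D"] <- d["N_D"] + g[["ND"]]
  }

  S_P <- NS + NR
  if (variant$p_saturation == "Pii") {
    den <- p$K_P + S_P
    attp_NS <- if (den > 0) p$a_P * P * NS / den else 0
    attp_NR <- if (den > 0) p$a_P * P * NR / den else 0
  } else {
    attp_NS <- p$a_P * P * NS
    attp_NR <- p$a_P * P * NR
  }
  A_P <- attp_NS + attp_NR
  d["N_S"] <- d["N_S"] - attp_NS
  if (has_NR) d["N_R"] <- d["N_R"] - attp_NR

  S_V <- NS + NP
  if (variant$v_saturation == "Vii") {
    den <- p$K_V + S_V
    attv_NS <- if (den > 0) p$a_V * V * NS / den else 0
    attv_NP <- if (den > 0) p$a_V * V * NP / den else 0
  } else {
    attv_NS <- p$a_V * V * NS
    attv_NP <- p$a_V * V * NP
  }
  A_V <- attv_NS + attv_NP
  d["N_S"] <- d["N_S"] - attv_NS
  if (has_NP) d["N_P"] <- d["N_P"] - attv_NP

  if (has_NP) {
    if (signal_conv) {
      conv_NS <- p$k_sig * C * NS
      conv_NR <- if (has_ND) p$k_sig * C * NR else 0
    } else {
      conv_NS <- p$r_I * NS
      conv_NR <- if (has_ND) p$r_I * NR else 0
    }
    d["N_S"] <- d["N_S"] - conv_NS
    d["N_P"] <- d["N_P"] + conv_NS
    if (has_ND) {
      d["N_R"] <- d["N_R"] - conv_NR
      d["N_D"] <- d["N_D"] + conv_NR
    }
    if (!growth_back) {
      d["N_P"] <- d["N_P"] - p$r_back * NP
      d["N_S"] <- d["N_S"] + p$r_back * NP
      if (has_ND) {
        d["N_D"] <- d["N_D"] - p$r_back * ND
        d["N_R"] <- d["N_R"] + p$r_back * ND
      }
    }
  }

  d["P"] <- p$beta_P * p$k_B * B - A_P - p$d_P * P
  d["B"] <- A_P - p$k_B * B
  d["V"] <- p$beta_V * p$k_I * I - A_V
  d["I"] <- A_V - p$k_I * I
  d["M"] <- -sum(g) + p$eps_B * p$k_B * B + p$eps_I * p$k_I * I
  if (signal_conv) {
    src <- switch(variant$signal_source, B_only = A_P, V_only = A_V, both = A_P + A_V)
    d["C"] <- p$sigma_C * src
  }

  inactive <- setdiff(copred_state_names(), active_compartments(variant))
  d[inactive] <- 0
  d
}

check_state <- function(state, variant) {
  nm <- copred_state_names()
  if (is.null(names(state))) {
    if (length(state) != 10) abort("State must have 10 compartments.")
    names(state) <- nm
  }
  if (!all(nm %in% names(state))) abort("State is missing compartments.")
  state <- state[nm]
  if (anyNA(state) || any(state < 0)) {
    abort("State compartments must be non-negative and non-missing.")
  }
  inactive <- setdiff(nm, active_compartments(variant))
  if (any(state[inactive] > 0)) {
    abort(paste0("Compartment(s) ", paste(inactive[state[inactive] > 0], collapse = ", "),
                 " are excluded by this variant but are non-zero."))
  }
  state
}

#' Integrate the dual-predation model
#'
#' Solves the variant's ODE system with a stiff-capable adaptive integrator
#' (deSolve's `lsoda`, compiled right-hand side). The trajectory is clamped
#' at zero after integration and densities below `1e-12`/ml are reported as
#' exactly zero. The result is bit-reproducible for fixed inputs and solver
#' options.
#'
#' @param variant A `copred_variant`.
#' @param params A `copred_params`.
#' @param init Initial state; defaults to [initial_state()] for `condition`.
#' @param times Output time grid in hours (strictly increasing, typically
#'   within 0--48).
#' @param condition Culture condition used when `init` is `NULL`.
#' @param solver_opts List with elements `rtol`, `atol`, `maxsteps`,
#'   `method` overriding the defaults `1e-8`, `1e-8`, `1e5`, `"lsoda"`.
#' @return A tibble of class `copred_trajectory` with column `time_h` and one
#'   column per compartment, carrying the variant, parameters and solver
#'   options as attributes.
#' @examples
#' tr <- simulate_predation(reference_variant(), reference_parameters(),
#'                          condition = "dual", times = seq(0, 48, 2))
#' observables(tr)
#' @export
simulate_predation <- function(variant, params, init = NULL,
                               times = seq(0, 48, by = 0.5),
                               condition = "dual",
                               solver_opts = list()) {
  stopifnot(inherits(variant, "copred_variant"))
  validate_params(params)
  cond_used <- if (is.null(init)) condition else NA_character_
  if (is.null(init)) init <- initial_state(params, condition, variant)
  init <- check_state(init, variant)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing with at least two points.")
  }
  opts <- modifyList(list(rtol = 1e-8, atol = 1e-8, maxsteps = 1e5,
                          method = "lsoda"), solver_opts)
  pvec <- c(unlist(params[.copred_par_names[1:18]]), variant_flags(variant))

  out <- deSolve::ode(
    y = unname(init), times = times, func = "copred_derivs", parms = pvec,
    dllname = "copred", initfunc = "copred_init",
    method = opts$method, rtol = opts$rtol, atol = opts$atol,
    maxsteps = opts$maxsteps
  )
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    abort(
      paste0("ODE integration failed (istate = ", istate[1],
             ") for variant ", variant_label(variant), " with parameters: ",
             paste(sprintf("%s=%.4g", .copred_par_names,
                           unlist(params[.copred_par_names])), collapse = ", ")),
      class = "copred_integration_error"
    )
  }
  if (nrow(out) < length(times)) {
    abort("ODE integration terminated early.", class = "copred_integration_error")
  }
  states <- out[, -1, drop = FALSE]
  states[states < 1e-12] <- 0
  colnames(states) <- copred_state_names()
  traj <- as_tibble(cbind(data.frame(time_h = out[, 1]), as.data.frame(states)))
  structure(traj,
            class = c("copred_trajectory", class(traj)),
            variant = variant, params = params, solver_opts = opts,
            condition = cond_used)
}

#' Experiment-comparable observables of a trajectory
#'
#' Maps model compartments onto what the plating assays count: prey CFU are
#' all prey subtypes; Bdellovibrio PFU are free cells plus bdelloplasts (both
#' seed a plaque); phage PFU are free virions plus infected cells.
#'
#' @param traj A `copred_trajectory` (or any data frame with the compartment
#'   columns).
#' @return A tibble with columns `time_h`, `prey`, `bdellovibrio`, `phage`.
#' @export
observables <- function(traj) {
  need <- c("time_h", copred_state_names())
  if (!all(need %in% names(traj))) abort("Not a model trajectory.")
  tibble(
    time_h = traj$time_h,
    prey = traj$N_S + traj$N_P + traj$N_R + traj$N_D,
    bdellovibrio = traj$P + traj$B,
    phage = traj$V + traj$I
  )
}
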