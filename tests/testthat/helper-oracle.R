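# Independent oracles, deliberately coded as a flux ledger: every process
# contributes (compartment, rate) entries which are summed at the end, rather
# than accumulating per-compartment derivatives as the implementation does.

oracle_derivs <- function(variant, params, state) {
  p <- unclass(params)
  s <- as.list(state[copred_state_names()])
  names(s) <- copred_state_names()
  fx <- list()
  add <- function(compartment, rate) {
    fx[[length(fx) + 1L]] <<- list(comp = compartment, rate = rate)
  }

  has_NR <- variant$prey_types %in% c("N2", "N3", "N4")
  has_NP <- variant$prey_types %in% c("N3", "N4")
  has_ND <- variant$prey_types == "N4"
  signal <- isTRUE(variant$conversion %in% c("S", "SG"))
  gback <- isTRUE(variant$conversion %in% c("IG", "SG"))
  de_novo <- has_NR && isTRUE(variant$resistance_origin %in% c("de_novo", "both"))

  monod <- p$mu_max * s$M / (p$K_M + s$M)
  if (s$M <= 0) monod <- 0

  # growth and division-coupled transitions, one prey subtype at a time
  grow <- function(x_name, offspring_to, mutant_to) {
    gx <- monod * s[[x_name]]
    add("M", -gx)
    frac <- if (de_novo && !is.null(mutant_to)) p$m else 0
    add(offspring_to, (1 - frac) * gx)
    if (frac > 0) add(mutant_to, frac * gx)
  }
  grow("N_S", "N_S", if (has_NR) "N_R")
  if (has_NP) grow("N_P", if (gback) "N_S" else "N_P", if (has_ND) "N_D")
  if (has_NR) grow("N_R", "N_R", NULL)
  if (has_ND) grow("N_D", if (gback) "N_R" else "N_D", NULL)

  # Bdellovibrio attack
  sus_p <- s$N_S + s$N_R
  p_rate <- function(x) {
    if (variant$p_saturation == "Pii") p$a_P * s$P * x / (p$K_P + sus_p)
    else p$a_P * s$P * x
  }
  att_p <- c(N_S = p_rate(s$N_S), N_R = if (has_NR) p_rate(s$N_R) else 0)
  for (nm in names(att_p)) {
    if (att_p[[nm]] > 0 || nm == "N_S") {
      add(nm, -att_p[[nm]])
    }
  }
  add("P", -sum(att_p))
  add("B", sum(att_p))

  # phage attack
  sus_v <- s$N_S + s$N_P
  v_rate <- function(x) {
    if (variant$v_saturation == "Vii") p$a_V * s$V * x / (p$K_V + sus_v)
    else p$a_V * s$V * x
  }
  att_v <- c(N_S = v_rate(s$N_S), N_P = if (has_NP) v_rate(s$N_P) else 0)
  add("N_S", -att_v[["N_S"]])
  if (has_NP) add("N_P", -att_v[["N_P"]])
  add("V", -sum(att_v))
  add("I", sum(att_v))

  # bdelloplast and infected-cell resolution
  add("B", -p$k_B * s$B)
  add("P", p$beta_P * p$k_B * s$B)
  add("M", p$eps_B * p$k_B * s$B)
  add("I", -p$k_I * s$I)
  add("V", p$beta_V * p$k_I * s$I)
  add("M", p$eps_I * p$k_I * s$I)

  # Bdellovibrio mortality
  add("P", -p$d_P * s$P)

  # phenotype conversions
  if (has_NP) {
    fwd <- function(x) if (signal) p$k_sig * s$C * x else p$r_I * x
    add("N_S", -fwd(s$N_S)); add("N_P", fwd(s$N_S))
    if (has_ND) {
      add("N_R", -fwd(s$N_R)); add("N_D", fwd(s$N_R))
    }
    if (!gback) {
      add("N_P", -p$r_back * s$N_P); add("N_S", p$r_back * s$N_P)
      if (has_ND) {
        add("N_D", -p$r_back * s$N_D); add("N_R", p$r_back * s$N_D)
      }
    }
  }

  # signal production
  if (signal) {
    src <- switch(variant$signal_source,
                  B_only = sum(att_p), V_only = sum(att_v),
                  both = sum(att_p) + sum(att_v))
    add("C", p$sigma_C * src)
  }

  out <- setNames(numeric(10), copred_state_names())
  for (f in fx) out[f$comp] <- out[f$comp] + f$rate
  out[setdiff(copred_state_names(), active_compartments(variant))] <- 0
  out
}

# classic fixed-step fourth-order Runge-Kutta on the oracle rates
oracle_rk4 <- function(variant, params, init, times, h = 1e-3) {
  f <- function(y) {
    y[y < 0] <- 0
    oracle_derivs(variant, params, y)
  }
  y <- init[copred_state_names()]
  out <- matrix(NA_real_, length(times), 10,
                dimnames = list(NULL, copred_state_names()))
  t <- times[1]
  out[1, ] <- y
  for (i in seq_along(times)[-1]) {
    while (t < times[i] - 1e-12) {
      step <- min(h, times[i] - t)
      k1 <- f(y)
      k2 <- f(y + step / 2 * k1)
      k3 <- f(y + step / 2 * k2)
      k4 <- f(y + step * k3)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[i, ] <- pmax(y, 0)
  }
  out
}

# random valid state / parameter helpers -------------------------------------

random_state <- function(variant, scale = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- setNames(runif(10, 0, scale), copred_state_names())
  s["C"] <- runif(1, 0, 5)
  s[setdiff(copred_state_names(), active_compartments(variant))] <- 0
  s
}

draw_from_prior <- function(variant, seed = NULL) {
  prior <- default_priors(variant)
  th <- sample_prior(prior, 1, seed = seed)$theta[[1]]
  parameter_set(base = reference_parameters(), c(prior$fixed, as.list(th)))
}

some_variants <- function() {
  list(
    model_variant("N1", p_saturation = "Pi"),
    model_variant("N2", resistance_origin = "de_novo"),
    model_variant("N3", conversion = "I", p_saturation = "Pi",
                  v_saturation = "Vii"),
    model_variant("N3", conversion = "IG"),
    model_variant("N3", conversion = "S", signal_source = "V_only"),
    reference_variant(),
    model_variant("N4", conversion = "SG", signal_source = "both",
                  mortality_mode = "fitted")
  )
}
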