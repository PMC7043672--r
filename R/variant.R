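#' Define a model variant of the dual-predation ODE family
#'
#' The model family shares one set of compartments (prey subtypes, free and
#' intracellular predators, medium, signal) and is specialised by discrete
#' choices: how many prey phenotypes exist, how sensitive prey convert to and
#' from plastic Bdellovibrio-resistant prey, where the conversion-inducing
#' signal comes from, whether phage resistance pre-exists or arises de novo
#' during growth, whether each predator's attack rate saturates in prey
#' density, and whether Bdellovibrio mortality is pinned to a literature value
#' or fitted.
#'
#' @param prey_types `"N1"` (sensitive prey only), `"N2"` (adds phage-resistant
#'   `N_R`), `"N3"` (adds plastic Bdellovibrio-resistant `N_P`) or `"N4"`
#'   (adds doubly resistant `N_D`).
#' @param conversion Conversion mechanism between `N_S` and `N_P`, one of
#'   `"I"` (intrinsic both ways), `"IG"` (intrinsic forward, growth-coupled
#'   back), `"S"` (signal-triggered forward, intrinsic back) or `"SG"`
#'   (signal-triggered forward, growth-coupled back). Only meaningful for
#'   `"N3"`/`"N4"`; must be `NULL` otherwise.
#' @param signal_source Which predator's attack flux produces the signal:
#'   `"B_only"`, `"V_only"` or `"both"`. Only meaningful when `conversion`
#'   involves a signal (`"S"`, `"SG"`).
#' @param resistance_origin Origin of phage resistance: `"preexisting"`,
#'   `"de_novo"` or `"both"`. Only meaningful for `"N2"`/`"N3"`/`"N4"`.
#' @param p_saturation `"Pi"` (mass-action Bdellovibrio attack) or `"Pii"`
#'   (Holling type-II saturation in total susceptible prey).
#' @param v_saturation `"Vi"` or `"Vii"`, likewise for the phage.
#' @param mortality_mode `"literature_fixed"` (Bdellovibrio mortality `d_P`
#'   pinned) or `"fitted"`.
#'
#' @return An object of class `copred_variant`.
#' @examples
#' model_variant("N3", conversion = "SG", signal_source = "B_only")
#' model_variant("N1")
#' @export
model_variant <- function(prey_types = c("N3", "N1", "N2", "N4"),
                          conversion = NULL,
                          signal_source = NULL,
                          resistance_origin = NULL,
                          p_saturation = c("Pii", "Pi"),
                          v_saturation = c("Vi", "Vii"),
                          mortality_mode = c("literature_fixed", "fitted")) {
  prey_types <- match.arg(prey_types)
  p_saturation <- match.arg(p_saturation)
  v_saturation <- match.arg(v_saturation)
  mortality_mode <- match.arg(mortality_mode)

  has_np <- prey_types %in% c("N3", "N4")
  has_nr <- prey_types %in% c("N2", "N3", "N4")

  if (has_np) {
    conversion <- conversion %||% "SG"
    conversion <- match.arg(conversion, c("I", "IG", "S", "SG"))
  } else if (!is.null(conversion)) {
    abort(sprintf("`conversion` is meaningless for prey_types = %s.", prey_types))
  }
  signal_conv <- isTRUE(conversion %in% c("S", "SG"))
  if (signal_conv) {
    signal_source <- signal_source %||% "B_only"
    signal_source <- match.arg(signal_source, c("B_only", "V_only", "both"))
  } else if (!is.null(signal_source)) {
    abort("`signal_source` is only meaningful for signal-driven conversion (S, SG).")
  }
  if (has_nr) {
    resistance_origin <- resistance_origin %||% "both"
    resistance_origin <- match.arg(resistance_origin, c("preexisting", "de_novo", "both"))
  } else if (!is.null(resistance_origin)) {
    abort(sprintf("`resistance_origin` is meaningless for prey_types = %s.", prey_types))
  }

  structure(
    list(
      prey_types = prey_types,
      conversion = conversion,
      signal_source = signal_source,
      resistance_origin = resistance_origin,
      p_saturation = p_saturation,
      v_saturation = v_saturation,
      mortality_mode = mortality_mode
    ),
    class = "copred_variant"
  )
}

#' The reference model variant
#'
#' Three prey phenotypes, signal-triggered conversion to plastic resistance
#' with the signal produced by Bdellovibrio attack only, growth-coupled back
#' conversion, both preexisting and de novo phage resistance, saturating
#' Bdellovibrio attack, non-saturating phage attack, literature-pinned
#' Bdellovibrio mortality. This is the variant the hierarchical competitions
#' are designed to recover from data generated by it.
#'
#' @return A `copred_variant`.
#' @export
reference_variant <- function() {
  model_variant("N3", conversion = "SG", signal_source = "B_only",
                resistance_origin = "both",
                p_saturation = "Pii", v_saturation = "Vi",
                mortality_mode = "literature_fixed")
}

#' @export
print.copred_variant <- function(x, ...) {
  cat("<copred_variant>", variant_label(x), "\n")
  invisible(x)
}

#' Compact label for a model variant
#'
#' E.g. `"N3-SBG-Pii-Vi"`: signal-triggered conversion with Bdellovibrio-only
#' signal source and growth-coupled back conversion.
#'
#' @param variant A `copred_variant`.
#' @return A string.
#' @export
variant_label <- function(variant) {
  conv <- ""
  if (!is.null(variant$conversion)) {
    src <- switch(variant$signal_source %||% "both",
                  B_only = "B", V_only = "V", both = "")
    conv <- switch(variant$conversion,
                   I = "I", IG = "IG",
                   S = paste0("S", src),
                   SG = paste0("S", src, "G"))
    conv <- paste0("-", conv)
  }
  res <- if (is.null(variant$resistance_origin)) "" else
    switch(variant$resistance_origin, preexisting = "-pre", de_novo = "-dnv", both = "")
  fit <- if (variant$mortality_mode == "fitted") "-dPfit" else ""
  paste0(variant$prey_types, conv, res, "-",
         variant$p_saturation, "-", variant$v_saturation, fit)
}

#' Which compartments are active under a variant
#'
#' @param variant A `copred_variant`.
#' @return Character vector of active compartment names (subset of
#'   `N_S, N_P, N_R, N_D, P, B, V, I, M, C`).
#' @export
active_compartments <- function(variant) {
  stopifnot(inherits(variant, "copred_variant"))
  out <- c("N_S", "P", "B", "V", "I", "M")
  if (variant$prey_types %in% c("N2", "N3", "N4")) out <- c(out, "N_R")
  if (variant$prey_types %in% c("N3", "N4")) out <- c(out, "N_P")
  if (variant$prey_types == "N4") out <- c(out, "N_D")
  if (isTRUE(variant$conversion %in% c("S", "SG"))) out <- c(out, "C")
  intersect(copred_state_names(), out)
}

# numeric flag encoding shared with the compiled right-hand side
variant_flags <- function(variant) {
  stopifnot(inherits(variant, "copred_variant"))
  c(
    prey_types = as.numeric(substr(variant$prey_types, 2, 2)),
    conversion = switch(variant$conversion %||% "I", I = 1, IG = 2, S = 3, SG = 4),
    signal_source = switch(variant$signal_source %||% "B_only",
                           B_only = 1, V_only = 2, both = 3),
    resistance_origin = switch(variant$resistance_origin %||% "preexisting",
                               preexisting = 1, de_novo = 2, both = 3),
    p_saturation = switch(variant$p_saturation, Pi = 1, Pii = 2),
    v_saturation = switch(variant$v_saturation, Vi = 1, Vii = 2)
  )
}

#' Compartment names of the state vector
#'
#' @return Character vector of the ten compartment names, in canonical order.
#' @export
copred_state_names <- function() {
  c("N_S", "N_P", "N_R", "N_D", "P", "B", "V", "I", "M", "C")
}
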