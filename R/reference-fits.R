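#' Synthetic reference fits of the N3 and N4 variants
#'
#' Typical parameter sets (PCA medoids, see [typical_parameter_set()])
#' obtained by fitting the three- and four-prey-type variants to the
#' package's default synthetic dataset ([generate_dataset()] with noise seed
#' 1) by ABC-SMC with 200 particles over 8 generations (SMC seed 20). They
#' are shipped frozen so that downstream predictions - most notably the
#' density of doubly resistant prey that the N4 equations predict under
#' either fit - are reproducible without re-running the fits. Both are
#' synthetic stand-ins for fits to real plate-count data: they characterise
#' the packaged generator's output, not any laboratory experiment.
#'
#' @param model `"N3"` or `"N4"`: which variant's fit to return.
#' @return A `copred_params`.
#' @seealso [reference_parameters()] for the generating (true) values.
#' @export
reference_fit_parameters <- function(model = c("N3", "N4")) {
  model <- match.arg(model)
  vals <- if (model == "N3") {
    list(
      mu_max = 0.34305183664590844,
      K_M = 2923496.9865302858,
      a_P = 8.0323922270130836,
      K_P = 692691.38102289382,
      a_V = 3.6462297500406698e-10,
      K_V = 1e9,
      k_B = 0.17393202877153183,
      beta_P = 3.2973628409277751,
      k_I = 1.4428283820941221,
      beta_V = 250.78645568878201,
      eps_B = 0.55716403114106816,
      eps_I = 0.24794901237998263,
      d_P = 0.03,
      sigma_C = 4.0894978458854574e-09,
      k_sig = 2.7444478976608616e-05,
      r_I = 1e-3,
      r_back = 1e-2,
      m = 8.2664150229607664e-06,
      f_R = 2.036147590079775e-07,
      N0 = 2.9e8, P0 = 2.8e6, V0 = 3.7e6,
      M0 = 13363189.442499161
    )
  } else {
    list(
      mu_max = 0.39330027516360888,
      K_M = 1989155.0435347378,
      a_P = 3.058517718297431,
      K_P = 7787630.3066532891,
      a_V = 3.4779914814689815e-10,
      K_V = 1e9,
      k_B = 0.02485020992641777,
      beta_P = 12.703898422305894,
      k_I = 1.273073543221442,
      beta_V = 202.88527783561108,
      eps_B = 0.89644989688629362,
      eps_I = 0.64329161017765668,
      d_P = 0.03,
      sigma_C = 8.0322916865776235e-08,
      k_sig = 1.1326015285523718e-05,
      r_I = 1e-3,
      r_back = 1e-2,
      m = 2.2171052266276235e-06,
      f_R = 1.1393080509065305e-05,
      N0 = 2.9e8, P0 = 2.8e6, V0 = 3.7e6,
      M0 = 64605686.336941957
    )
  }
  parameter_set(base = reference_parameters(), vals)
}
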