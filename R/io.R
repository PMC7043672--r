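# serialization helpers -------------------------------------------------------

variant_to_list <- function(variant) {
  purrr::compact(unclass(variant))
}

variant_from_list <- function(x) {
  model_variant(prey_types = x$prey_types,
                conversion = x$conversion %||% NULL,
                signal_source = x$signal_source %||% NULL,
                resistance_origin = x$resistance_origin %||% NULL,
                p_saturation = x$p_saturation %||% "Pii",
                v_saturation = x$v_saturation %||% "Vi",
                mortality_mode = x$mortality_mode %||% "literature_fixed")
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write / read a trajectory as tidy CSV plus a JSON sidecar
#'
#' The CSV holds `time_h`, `compartment`, `density_per_ml`; the sidecar (same
#' path with `.json`) holds the model variant, parameter set and solver
#' options so the trajectory round-trips bit-identically.
#'
#' @param traj A `copred_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the restored `copred_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "copred_trajectory"))
  long <- tidyr::pivot_longer(as_tibble(traj), -"time_h",
                              names_to = "compartment",
                              values_to = "density_per_ml")
  # 17 significant digits so that doubles survive the text round trip exactly
  long$density_per_ml <- sprintf("%.17g", long$density_per_ml)
  long$time_h <- sprintf("%.17g", long$time_h)
  readr::write_csv(long, path)
  meta <- list(
    variant = variant_to_list(attr(traj, "variant")),
    params = unclass(attr(traj, "params")),
    solver_opts = attr(traj, "solver_opts"),
    condition = attr(traj, "condition")
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  # base read.csv parses doubles with strtod, which inverts the 17-digit
  # formatting exactly (readr's parser can be one ulp off)
  long <- as_tibble(utils::read.csv(path, colClasses = c("numeric",
                                                         "character",
                                                         "numeric")))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  wide <- tidyr::pivot_wider(long, names_from = "compartment",
                             values_from = "density_per_ml")
  wide <- wide[c("time_h", copred_state_names())]
  structure(as_tibble(wide),
            class = c("copred_trajectory", class(as_tibble(wide))),
            variant = variant_from_list(meta$variant),
            params = parameter_set(base = reference_parameters(), meta$params),
            solver_opts = meta$solver_opts,
            condition = meta$condition)
}

#' Write / read a synthetic dataset as tidy CSV plus a JSON sidecar
#'
#' @param x A `copred_dataset`.
#' @param path CSV file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()` the
#'   restored `copred_dataset`.
#' @export
write_dataset <- function(x, path) {
  stopifnot(inherits(x, "copred_dataset"))
  readr::write_csv(as_tibble(x), path, na = "")
  meta <- list(
    design = unclass(attr(x, "design")),
    noise = unclass(attr(x, "noise")),
    variant = if (!is.null(attr(x, "variant"))) variant_to_list(attr(x, "variant")),
    params = if (!is.null(attr(x, "params"))) unclass(attr(x, "params"))
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         condition = readr::col_character(),
                         population = readr::col_character(),
                         time_h = readr::col_double(),
                         replicate = readr::col_integer(),
                         density_per_ml = readr::col_double(),
                         censored = readr::col_logical()
                       ))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  design <- do.call(experiment_design, meta$design)
  noise <- if (!is.null(meta$noise)) do.call(noise_model, meta$noise)
  variant <- if (!is.null(meta$variant)) variant_from_list(meta$variant)
  params <- if (!is.null(meta$params)) {
    parameter_set(base = reference_parameters(), meta$params)
  }
  new_copred_dataset(x, design = design, noise = noise, variant = variant,
                     params = params)
}

#' Write / read an ABC-SMC result
#'
#' Writes a JSON file (config, per-generation tolerances and acceptance
#' rates, model frequencies, priors) and a companion CSV of accepted
#' particles (`generation`, `model`, `weight`, `distance`, one column per
#' parameter).
#'
#' @param x A `copred_smc`.
#' @param path JSON file path; the particle CSV sits next to it with suffix
#'   `_particles.csv`.
#' @return `write_smc_result()` returns `path` invisibly; `read_smc_result()`
#'   the restored `copred_smc` (sufficient for [typical_parameter_set()] and
#'   the tidiers; distance closures are not restored).
#' @export
write_smc_result <- function(x, path) {
  stopifnot(inherits(x, "copred_smc"))
  particles <- tidy(x, generation = unique(x$particles$generation))
  csv <- paste0(tools::file_path_sans_ext(path), "_particles.csv")
  readr::write_csv(particles, csv)
  meta <- list(
    models = x$models,
    config = unclass(x$config),
    generations = x$generations,
    model_frequencies = x$model_frequencies,
    priors = purrr::map(x$priors, function(p) {
      list(bounds = p$bounds, fixed = p$fixed)
    }),
    variants = if (!is.null(x$variants)) purrr::map(x$variants, variant_to_list)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_smc_result
#' @export
read_smc_result <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  csv <- paste0(tools::file_path_sans_ext(path), "_particles.csv")
  particles <- readr::read_csv(csv, show_col_types = FALSE)
  priors <- purrr::map(meta$priors, function(p) {
    prior_spec(as_tibble(p$bounds), fixed = p$fixed)
  })
  par_cols <- setdiff(names(particles),
                      c("generation", "model", "weight", "distance"))
  theta <- purrr::map(seq_len(nrow(particles)), function(i) {
    v <- unlist(particles[i, par_cols])
    v[!is.na(v)]
  })
  plong <- tibble(
    generation = particles$generation, model = particles$model,
    weight = particles$weight, distance = particles$distance, theta = theta
  )
  structure(list(
    models = meta$models,
    priors = priors,
    config = do.call(smc_config, meta$config[c("n_particles", "alpha",
                                               "max_generations",
                                               "min_acceptance",
                                               "kernel_factor",
                                               "max_tries_factor", "seed")]),
    generations = as_tibble(meta$generations),
    particles = plong,
    model_frequencies = as_tibble(meta$model_frequencies),
    variants = if (!is.null(meta$variants)) purrr::map(meta$variants, variant_from_list)
  ), class = "copred_smc")
}

# flat `key = value` config ----------------------------------------------------

#' Read / write a flat `key = value` run configuration
#'
#' The configuration format is plain text, one `key = value` per line,
#' `#` comments allowed. Dots group keys into blocks, e.g.
#' `variant.prey_types = N3`, `params.mu_max = 0.6`,
#' `design.duration = 48`, `smc.n_particles = 200`, `seed = 1`. Values that
#' parse as numbers become numeric; `TRUE`/`FALSE` become logical; anything
#' else stays a string. Comma-separated values become vectors.
#'
#' @param path Config file path.
#' @return `read_run_config()`: a nested named list. `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) abort(paste0("Malformed config line (no '='): ", ln))
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!nzchar(key)) abort(paste0("Malformed config line (empty key): ", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) {
      num
    } else if (all(parts %in% c("TRUE", "FALSE", "true", "false"))) {
      toupper(parts) == "TRUE"
    } else {
      parts
    }
    keys <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(keys) == 1L) {
      out[[keys]] <- parsed
    } else if (length(keys) == 2L) {
      blk <- out[[keys[1]]] %||% list()
      blk[[keys[2]]] <- parsed
      out[[keys[1]]] <- blk
    } else {
      abort(paste0("Config keys nest at most one level: ", key))
    }
  }
  out
}

#' @rdname read_run_config
#' @param config A nested named list (depth at most two).
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) paste(vapply(v, function(x) {
    if (is.numeric(x)) format(x, digits = 17, scientific = TRUE) else as.character(x)
  }, character(1)), collapse = ", ")
  lines <- character(0)
  for (key in names(config)) {
    v <- config[[key]]
    if (is.list(v)) {
      for (sub in names(v)) {
        lines <- c(lines, paste0(key, ".", sub, " = ", fmt(v[[sub]])))
      }
    } else {
      lines <- c(lines, paste0(key, " = ", fmt(v)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
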