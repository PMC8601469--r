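#' Run / survey configuration
#'
#' Collects every knob of a run or a population survey in one validated
#' object that round-trips losslessly through YAML or JSON, so a simulation
#' is fully reconstructable from its configuration file.
#'
#' @param phi1,phi2 Numeric vectors of population densities and reactive
#'   fractions to survey (single values for a plain run).
#' @param N Lattice side length.
#' @param base_seed First seed; replicate `r` uses `base_seed + r - 1` for
#'   auditability.
#' @param n_replicates Independent realizations per `(phi1, phi2)` cell.
#' @param n_iter,record_every Iteration count and snapshot stride.
#' @param f_fire,u_fire Initial firing fraction and amplitude.
#' @param n_head,n_tail Analysis windows, see [fit_growth_line()].
#' @param classify Run the pattern classifier (requires field snapshots,
#'   costs memory)?
#' @param params A [model_params()] object.
#' @return A `camp_config` list.
#' @examples
#' cfg <- survey_config(phi1 = 0.5, phi2 = c(0, 0.1), N = 64, n_iter = 200)
#' @export
survey_config <- function(phi1 = 0.5, phi2 = 0, N = 400L, base_seed = 1L,
                          n_replicates = 1L, n_iter = 6000L,
                          record_every = 60L, f_fire = 0.01, u_fire = 1.0,
                          n_head = 300L, n_tail = 3000L, classify = TRUE,
                          params = model_params()) {
  stopifnot(
    is.numeric(phi1), length(phi1) >= 1L, all(phi1 >= 0 & phi1 <= 1),
    is.numeric(phi2), length(phi2) >= 1L, all(phi2 >= 0 & phi2 <= 1)
  )
  check_scalar(N, "N", lower = 2, integerish = TRUE)
  check_scalar(base_seed, "base_seed", integerish = TRUE)
  check_scalar(n_replicates, "n_replicates", lower = 1, integerish = TRUE)
  check_scalar(n_iter, "n_iter", lower = 1, integerish = TRUE)
  check_scalar(record_every, "record_every", lower = 1, integerish = TRUE)
  stopifnot(inherits(params, "camp_params"))
  structure(
    list(
      phi1 = phi1, phi2 = phi2, N = as.integer(N),
      base_seed = as.integer(base_seed),
      n_replicates = as.integer(n_replicates),
      n_iter = as.integer(n_iter), record_every = as.integer(record_every),
      f_fire = f_fire, u_fire = u_fire,
      n_head = as.integer(n_head), n_tail = as.integer(n_tail),
      classify = isTRUE(classify), params = params
    ),
    class = "camp_config"
  )
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$params <- unclass(out$params)
  out$params$bc_code <- NULL
  out
}

#' Read / write a configuration file
#'
#' Configurations serialize to a flat YAML or JSON document (chosen by the
#' file extension) with a nested `params` block mirroring [model_params()].
#'
#' @param config A [survey_config()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the reconstructed `camp_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "camp_config"))
  lst <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  par_lst <- lst$params
  if (!is.null(par_lst$u_cap) && is.character(par_lst$u_cap)) {
    par_lst$u_cap <- as.numeric(par_lst$u_cap)
  }
  if (is.null(par_lst$u_cap) || is.na(par_lst$u_cap)) par_lst$u_cap <- Inf
  params <- do.call(model_params, par_lst)
  lst$params <- NULL
  lst <- lst[!vapply(lst, is.null, logical(1))]
  do.call(survey_config, c(lst, list(params = params)))
}

#' Export the summary series of a run as CSV (+ JSON provenance sidecar)
#'
#' Writes one tidy row per iteration (`iteration, ubar, sigma, cov`) and a
#' `<path>.json` sidecar holding the resolved parameters, lattice settings
#' and seed, so the run can be reproduced from its outputs alone.
#'
#' @param trajectory A `camp_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "camp_trajectory"))
  write.csv(trajectory$series, path, row.names = FALSE)
  lat <- trajectory$lattice
  meta <- list(
    lattice = lat[c("N", "phi1", "phi2", "seed")],
    params = config_to_list(list(params = trajectory$params))$params,
    seed = trajectory$seed, n_iter = trajectory$n_iter,
    record_every = trajectory$record_every
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
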