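#' Run one configured simulation and summarize it
#'
#' Convenience wrapper: lattice generation, integration and analysis for a
#' single `(phi1, phi2, seed)` cell of a configuration.
#'
#' @param config A [survey_config()] (its *first* `phi1`/`phi2` entries are
#'   used unless overridden).
#' @param phi1,phi2,seed Optional overrides of the configured values.
#' @param record_fields Keep field snapshots (needed for classification /
#'   kymographs)?
#' @return A `camp_trajectory`.
#' @export
run_cell <- function(config, phi1 = NULL, phi2 = NULL, seed = NULL,
                     record_fields = config$classify) {
  stopifnot(inherits(config, "camp_config"))
  phi1 <- phi1 %||% config$phi1[1]
  phi2 <- phi2 %||% config$phi2[1]
  seed <- seed %||% config$base_seed
  lat <- generate_lattice(config$N, phi1, phi2, seed = seed)
  simulate_population(
    lat, config$params,
    n_iter = config$n_iter, record_every = config$record_every,
    seed = seed, record_fields = record_fields,
    f_fire = config$f_fire, u_fire = config$u_fire
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Survey the (phi1, phi2) composition plane
#'
#' Runs `simulate -> analyze -> classify` for every combination of
#' population density `phi1`, reactive fraction `phi2` and replicate in the
#' configuration, and returns one tidy row per run: the synchrony index
#' `S`, the oscillatory-regime mean field `ubar_osc`, the growth `slope`,
#' the `crossover` iteration and the advisory pattern `label`. A failing
#' cell (e.g. a dead medium where the synchrony index is undefined) is
#' reported in its `error` column and never aborts the sweep. Replicate `r`
#' uses seed `base_seed + r - 1`.
#'
#' @param config A [survey_config()].
#' @param progress Print one line per finished run?
#' @return A tibble with one row per `(phi1, phi2, replicate)`.
#' @examples
#' cfg <- survey_config(
#'   phi1 = 0.5, phi2 = c(0, 0.5), N = 48, n_iter = 300,
#'   n_head = 100, n_tail = 100, classify = FALSE
#' )
#' run_survey(cfg)
#' @export
run_survey <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "camp_config"))
  grid <- tidyr::expand_grid(
    phi1 = config$phi1, phi2 = config$phi2,
    replicate = seq_len(config$n_replicates)
  )
  purrr::pmap_dfr(grid, function(phi1, phi2, replicate) {
    seed <- config$base_seed + replicate - 1L
    base <- tibble::tibble(
      phi1 = phi1, phi2 = phi2, replicate = replicate, seed = seed,
      N = config$N
    )
    row <- tryCatch(
      {
        tr <- run_cell(config,
          phi1 = phi1, phi2 = phi2, seed = seed,
          record_fields = config$classify
        )
        an <- analyze_trajectory(tr,
          n_head = config$n_head,
          n_tail = config$n_tail
        )
        label <- if (config$classify) {
          classify_pattern(tr)$label
        } else {
          NA_character_
        }
        dplyr::bind_cols(
          base,
          an[c("S", "ubar_osc", "slope", "intercept", "plateau", "crossover")],
          tibble::tibble(label = label, error = NA_character_)
        )
      },
      error = function(e) {
        dplyr::bind_cols(
          base,
          tibble::tibble(
            S = NA_real_, ubar_osc = NA_real_, slope = NA_real_,
            intercept = NA_real_, plateau = NA_real_, crossover = NA_real_,
            label = NA_character_, error = conditionMessage(e)
          )
        )
      }
    )
    if (progress) {
      message(sprintf(
        "phi1 = %.2f, phi2 = %.2f, rep %d: S = %s",
        phi1, phi2, replicate,
        ifelse(is.na(row$S), paste0("failed (", row$error, ")"),
          sprintf("%.4f", row$S)
        )
      ))
    }
    row
  })
}

#' Tiny deterministic fixture lattices
#'
#' Emits the small lattices used in examples and tests: a pure 6x6 lattice,
#' a mixed 8x8 lattice and an empty 4x4 one, each with its JSON provenance
#' sidecar. Handy as known-good inputs when scripting against the package.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_fixture_lattices <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  specs <- list(
    pure_6x6 = list(N = 6, phi1 = 1, phi2 = 0, seed = 1),
    mixed_8x8 = list(N = 8, phi1 = 0.5, phi2 = 0.25, seed = 2),
    empty_4x4 = list(N = 4, phi1 = 0, phi2 = 0, seed = 3)
  )
  paths <- purrr::imap_chr(specs, function(sp, nm) {
    lat <- generate_lattice(sp$N, sp$phi1, sp$phi2, seed = sp$seed)
    write_lattice(lat, file.path(dir, paste0(nm, ".txt")))
    file.path(dir, paste0(nm, ".txt"))
  })
  invisible(paths)
}
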