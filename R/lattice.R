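#' Generate a random mixed-population lattice
#'
#' Places cells uniformly at random on an `N x N` square lattice. A fraction
#' `phi1` of the `N^2` sites is occupied (counts are exact:
#' `round(phi1 * N^2)` sites, sampled without replacement), and a fraction
#' `phi2` *of the occupied sites* (`round(phi2 * n_occupied)`, again exact)
#' is labelled reactive/less-cooperative; the rest are
#' proactive/cooperative. Cells do not move during a simulation.
#'
#' @param N Lattice side length (grid is `N x N`), integer `>= 2`.
#' @param phi1 Fraction of all lattice sites occupied by cells, in `[0, 1]`.
#' @param phi2 Fraction of the *occupied* sites that are reactive, in
#'   `[0, 1]`.
#' @param seed Integer seed; the lattice is reproducible given
#'   `(N, phi1, phi2, seed)`. The caller's RNG state is left untouched.
#' @return A `camp_lattice`: list with `N`, `phi1`, `phi2`, `seed` and
#'   `type_map`, an `N x N` integer matrix with entries 0 (`EMPTY`),
#'   1 (`PROACTIVE`), 2 (`REACTIVE`).
#' @examples
#' lat <- generate_lattice(50, phi1 = 0.5, phi2 = 0.1, seed = 1)
#' table(lat$type_map)
#' @export
generate_lattice <- function(N, phi1, phi2, seed = 1L) {
  check_scalar(N, "N", lower = 2, integerish = TRUE)
  check_scalar(phi1, "phi1", lower = 0, upper = 1)
  check_scalar(phi2, "phi2", lower = 0, upper = 1)
  check_scalar(seed, "seed", integerish = TRUE)
  N <- as.integer(N)

  n_sites <- N * N
  n_occ <- round(phi1 * n_sites)
  n_react <- round(phi2 * n_occ)

  type_map <- matrix(TYPE_EMPTY, N, N)
  with_seed(seed, {
    occ <- sample.int(n_sites, n_occ)
    type_map[occ] <- TYPE_PROACTIVE
    if (n_react > 0) {
      # index into occ explicitly: sample(x, n) on a length-1 x would
      # resample from 1:x
      type_map[occ[sample.int(n_occ, n_react)]] <- TYPE_REACTIVE
    }
  })

  structure(
    list(N = N, phi1 = phi1, phi2 = phi2, seed = as.integer(seed),
         type_map = type_map),
    class = "camp_lattice"
  )
}

#' Count cells by type
#'
#' @param lattice A [generate_lattice()] result.
#' @return A tibble with one row per type (`EMPTY`, `PROACTIVE`,
#'   `REACTIVE`) and its site count.
#' @export
lattice_counts <- function(lattice) {
  stopifnot(inherits(lattice, "camp_lattice"))
  tm <- lattice$type_map
  tibble::tibble(
    type = type_labels,
    count = c(
      sum(tm == TYPE_EMPTY), sum(tm == TYPE_PROACTIVE),
      sum(tm == TYPE_REACTIVE)
    )
  )
}

#' @export
print.camp_lattice <- function(x, ...) {
  n_occ <- sum(x$type_map != TYPE_EMPTY)
  cat(sprintf(
    "<camp_lattice> %d x %d, phi1 = %g, phi2 = %g (seed %d)\n",
    x$N, x$N, x$phi1, x$phi2, x$seed
  ))
  cat(sprintf(
    "  %d occupied sites (%d proactive, %d reactive)\n",
    n_occ, sum(x$type_map == TYPE_PROACTIVE), sum(x$type_map == TYPE_REACTIVE)
  ))
  invisible(x)
}

#' Initial field state with randomly firing cells
#'
#' Builds the state at iteration 0: a randomly chosen fraction `f_fire` of
#' the *occupied* sites starts excited at activator level `u_fire`
#' (`round(f_fire * n_occupied)` sites, exact count), all other sites start
#' at rest (`u = 0`), and the recovery variable `v` and noise `eta` are 0
#' everywhere. `u` lives on the whole grid (cAMP diffuses through the
#' medium); `v` and `eta` are meaningful only on occupied sites and are held
#' at 0 on empty ones.
#'
#' @param lattice A [generate_lattice()] result.
#' @param f_fire Fraction of occupied cells initially excited, in `[0, 1]`.
#' @param u_fire Activator level given to firing cells; must exceed `delta`
#'   when any cell fires, otherwise the "firing" cells would sit inside the
#'   rest boundary layer and the medium would be silently dead.
#' @param seed Integer seed for the choice of firing cells.
#' @param delta Boundary-layer size used for the `u_fire` validity check
#'   (match the `delta` in your [model_params()]).
#' @return A `camp_state`: list with matrices `u`, `v`, `eta` and the
#'   counter `iteration = 0`.
#' @examples
#' lat <- generate_lattice(50, 0.5, 0, seed = 1)
#' st <- initialize_state(lat, f_fire = 0.02, seed = 2)
#' sum(st$u > 0)
#' @export
initialize_state <- function(lattice, f_fire = 0.01, u_fire = 1.0,
                             seed = 1L, delta = 1e-4) {
  stopifnot(inherits(lattice, "camp_lattice"))
  check_scalar(f_fire, "f_fire", lower = 0, upper = 1)
  check_scalar(u_fire, "u_fire")
  check_scalar(seed, "seed", integerish = TRUE)

  occ <- which(lattice$type_map != TYPE_EMPTY)
  n_fire <- round(f_fire * length(occ))
  if (n_fire > 0 && u_fire <= delta) {
    stop(
      "`u_fire` (", u_fire, ") must exceed the boundary layer delta (",
      delta, "): firing cells would not be excited",
      call. = FALSE
    )
  }

  N <- lattice$N
  u <- matrix(0, N, N)
  if (n_fire > 0) {
    with_seed(seed, {
      u[occ[sample.int(length(occ), n_fire)]] <- u_fire
    })
  }
  structure(
    list(u = u, v = matrix(0, N, N), eta = matrix(0, N, N), iteration = 0L),
    class = "camp_state"
  )
}

#' @export
print.camp_state <- function(x, ...) {
  cat(sprintf(
    "<camp_state> %d x %d at iteration %d; mean u = %.4g, max u = %.4g\n",
    nrow(x$u), ncol(x$u), x$iteration, mean(x$u), max(x$u)
  ))
  invisible(x)
}

#' Write / read a lattice as plain text with a JSON provenance sidecar
#'
#' The type map is written as a whitespace-separated integer matrix and a
#' `<path>.json` sidecar records `(N, phi1, phi2, seed)` so the lattice can
#' be regenerated or audited.
#'
#' @param lattice A `camp_lattice`.
#' @param path Output path for the matrix; the sidecar is `<path>.json`.
#' @return `write_lattice()` returns `path` invisibly; `read_lattice()`
#'   returns the reconstructed `camp_lattice`.
#' @export
write_lattice <- function(lattice, path) {
  stopifnot(inherits(lattice, "camp_lattice"))
  write.table(lattice$type_map, path,
    row.names = FALSE, col.names = FALSE
  )
  jsonlite::write_json(
    lattice[c("N", "phi1", "phi2", "seed")],
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tm <- as.matrix(read.table(path))
  dimnames(tm) <- NULL
  storage.mode(tm) <- "integer"
  stopifnot(nrow(tm) == meta$N, ncol(tm) == meta$N)
  structure(
    list(N = as.integer(meta$N), phi1 = meta$phi1, phi2 = meta$phi2,
         seed = as.integer(meta$seed), type_map = tm),
    class = "camp_lattice"
  )
}
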