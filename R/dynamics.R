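#' Local kinetics of the two cell types
#'
#' `u_threshold()` returns the excitation threshold
#' \eqn{u_{th} = (v + b)/a}. `proactive_rate()` is the cubic Barkley
#' reaction rate of cooperative cells,
#' \eqn{\epsilon^{-1} u (1 - u)(u - u_{th})}; its roots at `u = 0`, `u = 1`
#' and `u = u_th` are the rest state, the excited plateau and the unstable
#' threshold. `reactive_rate()` is the linear rate \eqn{u - u_{th}} of
#' less-cooperative cells; the missing \eqn{1/\epsilon} factor makes their
#' response slower.
#'
#' All three are vectorized over `u` and `v`.
#'
#' @param u Activator (extracellular cAMP) level(s).
#' @param v Recovery-variable level(s).
#' @param params A [model_params()] object.
#' @return Numeric vector of thresholds or reaction rates.
#' @examples
#' p <- model_params(a = 0.8, b = 0.05)
#' u_threshold(0, p)
#' proactive_rate(c(0, 1), 0, p)
#' @export
u_threshold <- function(v, params) {
  stopifnot(inherits(params, "camp_params"))
  (v + params$b) / params$a
}

#' @rdname u_threshold
#' @export
proactive_rate <- function(u, v, params) {
  stopifnot(inherits(params, "camp_params"))
  u * (1 - u) * (u - u_threshold(v, params)) / params$epsilon
}

#' @rdname u_threshold
#' @export
reactive_rate <- function(u, v, params) {
  stopifnot(inherits(params, "camp_params"))
  u - u_threshold(v, params)
}

#' One exact Ornstein-Uhlenbeck step
#'
#' Advances colored noise \eqn{\eta} by one time step `params$dt` using the
#' exact discretization of
#' \eqn{\partial\eta/\partial t = -\lambda \eta + \sqrt{2 D \lambda}\,\zeta(t)}:
#' \deqn{\eta' = \eta e^{-\lambda \Delta t} +
#'   \sqrt{D (1 - e^{-2 \lambda \Delta t})} \, z, \quad z \sim N(0, 1),}
#' so the update is unbiased at any step size; the stationary law is
#' `N(0, D)` and the autocorrelation at lag \eqn{\tau} is
#' \eqn{e^{-\lambda\tau}}. Vectorized over `eta` with independent draws per
#' element; uses the current R RNG stream.
#'
#' @param eta Current noise value(s).
#' @param params A [model_params()] object (`D`, `lam`, `dt` are used).
#' @return Updated noise value(s), same shape as `eta`.
#' @examples
#' p <- model_params(D = 0, lam = 2, dt = 0.5, D_u = 0.5)
#' ou_update(1, p) # deterministic decay exp(-1)
#' @export
ou_update <- function(eta, params) {
  stopifnot(inherits(params, "camp_params"))
  rho <- exp(-params$lam * params$dt)
  eta * rho + sqrt(params$D * (1 - rho^2)) * rnorm(length(eta))
}

#' Discrete 5-point Laplacian
#'
#' Standard second-order stencil
#' \eqn{(\sum_{nbr} u - 4u)/h^2} over the four von Neumann neighbors.
#' Under `"noflux"` boundaries an out-of-grid neighbor takes the edge value
#' (zero normal gradient); under `"periodic"` the index wraps around.
#'
#' @param field Numeric matrix.
#' @param bc `"noflux"` or `"periodic"`.
#' @param h Lattice spacing.
#' @return Matrix of the same dimensions.
#' @examples
#' laplacian(matrix(1, 4, 4)) # all zeros
#' @export
laplacian <- function(field, bc = c("noflux", "periodic"), h = 1) {
  bc <- match.arg(bc)
  stopifnot(is.matrix(field), is.numeric(field))
  check_scalar(h, "h")
  laplacian_cpp(field, bc_code(bc), h)
}

#' Advance the field state by one (or more) time steps
#'
#' Applies one `dt` update of the full stochastic reaction-diffusion
#' system. Per-site contract: empty sites only diffuse `u`; proactive sites
#' inside the boundary layer (`u < delta`) skip the reaction but still
#' diffuse; proactive sites with `u >= delta` take a semi-implicit Barkley
#' update of the cubic kinetics (the `(u - u_th)` factor is frozen over the
#' step and the remaining logistic part is treated implicitly, which keeps
#' the stiff \eqn{1/\epsilon} term stable); reactive sites take an explicit
#' Euler step of the linear kinetics. On every occupied site
#' `v <- v + dt * (u - v + eta)` and `eta` advances by one exact
#' Ornstein-Uhlenbeck step. Noise never enters `u` directly or empty sites.
#'
#' Draws from the current R RNG stream; wrap in [set.seed()] (or use
#' [simulate_population()]) for reproducibility.
#'
#' @param state A `camp_state` (see [initialize_state()]).
#' @param lattice The matching `camp_lattice`.
#' @param params A [model_params()] object.
#' @param n_steps Number of consecutive steps to take (default 1).
#' @return The advanced `camp_state`.
#' @export
step_state <- function(state, lattice, params, n_steps = 1L) {
  stopifnot(
    inherits(state, "camp_state"), inherits(lattice, "camp_lattice"),
    inherits(params, "camp_params")
  )
  check_scalar(n_steps, "n_steps", lower = 1, integerish = TRUE)
  if (!all(dim(state$u) == dim(lattice$type_map))) {
    stop("state and lattice dimensions differ", call. = FALSE)
  }
  res <- advance_cpp(
    lattice$type_map, state$u, state$v, state$eta,
    unclass(params), as.integer(n_steps),
    record_every = as.integer(n_steps), record_fields = FALSE,
    kymo_row = lattice$N %/% 2L, iter0 = state$iteration
  )
  structure(
    list(u = res$u, v = res$v, eta = res$eta,
         iteration = state$iteration + as.integer(n_steps)),
    class = "camp_state"
  )
}

#' Simulate the mixed-population excitable medium
#'
#' Runs the stochastic two-type reaction-diffusion system for `n_iter`
#' steps from a randomly seeded firing state (or a supplied `init` state),
#' recording after every iteration the spatial mean `ubar`, the spatial
#' standard deviation `sigma` and the von Neumann neighbor covariance `cov`
#' of `u`, plus one lattice row of `u` (for kymographs) and full `u`/`v`
#' snapshots every `record_every` iterations. Runs are bit-reproducible
#' given `(lattice, params, seed)`.
#'
#' @param lattice A [generate_lattice()] result.
#' @param params A [model_params()] object.
#' @param n_iter Number of integration steps (`>= 1`).
#' @param record_every Snapshot stride in iterations (the last iteration is
#'   always included). Default 60.
#' @param seed Integer seed governing the initial firing pattern and every
#'   noise draw.
#' @param record_fields Keep full-field snapshots? Set `FALSE` to save
#'   memory when only summary series are needed.
#' @param init Optional `camp_state` to start from; when supplied,
#'   `f_fire`/`u_fire` are ignored.
#' @param f_fire,u_fire Initial firing fraction (of occupied cells) and
#'   amplitude, passed to [initialize_state()].
#' @param kymo_row Row (1-based) whose `u` values are recorded every
#'   iteration; default the middle row `N %/% 2`.
#' @return A `camp_trajectory`: list with `series` (a tibble
#'   `iteration, ubar, sigma, cov`), `midrow` (iterations x N matrix),
#'   `snapshots` (`u`, `v`, `iterations`), the final `state`, and the
#'   `lattice`/`params`/`seed` provenance.
#' @examples
#' lat <- generate_lattice(32, 0.5, 0.1, seed = 1)
#' tr <- simulate_population(lat, model_params(), n_iter = 50, seed = 1)
#' tidy(tr)
#' @export
simulate_population <- function(lattice, params = model_params(), n_iter,
                                record_every = 60L, seed = 1L,
                                record_fields = TRUE, init = NULL,
                                f_fire = 0.01, u_fire = 1.0,
                                kymo_row = NULL) {
  stopifnot(inherits(lattice, "camp_lattice"), inherits(params, "camp_params"))
  check_scalar(n_iter, "n_iter", lower = 1, integerish = TRUE)
  check_scalar(record_every, "record_every", lower = 1, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  if (is.null(kymo_row)) kymo_row <- max(1L, lattice$N %/% 2L)
  check_scalar(kymo_row, "kymo_row", lower = 1, upper = lattice$N,
    integerish = TRUE
  )

  if (is.null(init)) {
    init <- initialize_state(lattice,
      f_fire = f_fire, u_fire = u_fire,
      seed = seed, delta = params$delta
    )
  } else {
    stopifnot(inherits(init, "camp_state"))
    if (!all(dim(init$u) == dim(lattice$type_map))) {
      stop("init state and lattice dimensions differ", call. = FALSE)
    }
  }

  res <- with_seed(seed, {
    advance_cpp(
      lattice$type_map, init$u, init$v, init$eta, unclass(params),
      as.integer(n_iter), as.integer(record_every),
      isTRUE(record_fields), as.integer(kymo_row) - 1L,
      iter0 = init$iteration
    )
  })

  structure(
    list(
      series = tibble::tibble(
        iteration = res$iterations, ubar = res$ubar,
        sigma = res$sigma, cov = res$cov
      ),
      midrow = res$midrow,
      kymo_row = as.integer(kymo_row),
      snapshots = list(
        u = res$snapshots_u, v = res$snapshots_v,
        iterations = res$snap_iterations
      ),
      state = structure(
        list(u = res$u, v = res$v, eta = res$eta,
             iteration = init$iteration + as.integer(n_iter)),
        class = "camp_state"
      ),
      lattice = lattice, params = params, seed = as.integer(seed),
      n_iter = as.integer(n_iter), record_every = as.integer(record_every),
      f_fire = if (is.null(init$f_fire)) f_fire else NA_real_,
      u_fire = u_fire
    ),
    class = "camp_trajectory"
  )
}

#' @export
print.camp_trajectory <- function(x, ...) {
  cat(sprintf(
    "<camp_trajectory> %d iterations on a %d x %d lattice (phi1 = %g, phi2 = %g, seed %d)\n",
    x$n_iter, x$lattice$N, x$lattice$N, x$lattice$phi1, x$lattice$phi2, x$seed
  ))
  cat(sprintf(
    "  %d field snapshots (stride %d); final mean u = %.4g\n",
    length(x$snapshots$iterations), x$record_every, mean(x$state$u)
  ))
  invisible(x)
}

#' @describeIn simulate_population Tidy per-iteration summary series
#'   (`iteration`, `ubar`, `sigma`, `cov`) of a trajectory.
#' @param x A `camp_trajectory`.
#' @param ... Unused.
#' @method tidy camp_trajectory
#' @export
tidy.camp_trajectory <- function(x, ...) {
  x$series
}
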