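#' Model parameters for the excitable lattice
#'
#' Bundles every kinetic, stochastic and numerical parameter of the
#' two-variable excitable medium. Proactive cells follow the cubic Barkley
#' kinetics \eqn{f(u,v) = \epsilon^{-1} u (1-u)(u - u_{th})} with threshold
#' \eqn{u_{th} = (v+b)/a}; reactive cells follow the linear kinetics
#' \eqn{u - u_{th}} (no \eqn{\epsilon}, hence slower); the recovery variable
#' obeys \eqn{\partial v/\partial t = u - v + \eta} where \eqn{\eta} is an
#' Ornstein-Uhlenbeck process of intensity `D` and correlation time `1/lam`.
#'
#' The default kinetic and noise values are a documented calibration to the
#' circular-wave (target-pattern) regime: a pure population at occupancy
#' 0.4 or above produces repeated noise-nucleated circular waves rather than
#' bulk oscillation or silence. See the methods vignette for the calibration
#' protocol.
#'
#' @param a,b Excitation threshold controls; the threshold is
#'   \eqn{u_{th} = (v + b)/a}. `a` must be positive.
#' @param epsilon Time-scale ratio of the fast activator `u` to the slow
#'   recovery variable `v` (dimensionless, `0 < epsilon << 1`).
#' @param delta Boundary-layer size: a site with `u < delta` is treated as
#'   at rest and its (cubic) reaction is skipped. A cell counts as *excited*
#'   when `u > delta`.
#' @param D Ornstein-Uhlenbeck noise intensity (stationary variance of
#'   \eqn{\eta}).
#' @param lam Ornstein-Uhlenbeck rate \eqn{\lambda} (inverse correlation
#'   time). The calibrated default (2, i.e. a correlation time of half a
#'   time unit) lets threshold dips last long enough to nucleate pacemakers
#'   while still mean-reverting within a recovery period; see
#'   [noise_preset()] for the limiting presets.
#' @param dt Integration time step.
#' @param h Lattice spacing (length unit of the grid).
#' @param D_u Diffusion coefficient of the activator `u`.
#' @param bc Boundary condition, `"noflux"` (default; out-of-grid neighbors
#'   mirror the edge value) or `"periodic"`.
#' @param decay Optional linear degradation rate of `u` on *empty* sites
#'   (default 0: extracellular cAMP only diffuses there).
#' @param u_cap Optional guard ceiling: the integrator aborts with a
#'   diagnostic if `|u|` ever exceeds it. Default `Inf` (disabled); the
#'   integrator always aborts on non-finite values regardless.
#' @param shared_noise If `TRUE` all occupied sites share one noise draw per
#'   step (sensitivity-analysis mode); default `FALSE`, independent noise
#'   per cell.
#'
#' @return An object of class `camp_params` (a validated named list).
#' @examples
#' p <- model_params()
#' u_threshold(0, p)
#' @export
model_params <- function(a = 0.8, b = 0.07, epsilon = 0.02, delta = 1e-4,
                         D = 0.03, lam = 2, dt = 0.01, h = 1,
                         D_u = 4, bc = c("noflux", "periodic"), decay = 0,
                         u_cap = Inf, shared_noise = FALSE) {
  bc <- match.arg(bc)
  check_scalar(a, "a")
  if (a <= 0) stop("`a` must be > 0 (the threshold (v + b)/a requires it)", call. = FALSE)
  check_scalar(b, "b")
  check_scalar(epsilon, "epsilon")
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  check_scalar(delta, "delta")
  if (delta <= 0) stop("`delta` must be > 0", call. = FALSE)
  check_scalar(D, "D", lower = 0)
  check_scalar(lam, "lam", lower = 0)
  check_scalar(dt, "dt")
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  check_scalar(h, "h")
  if (h <= 0) stop("`h` must be > 0", call. = FALSE)
  check_scalar(D_u, "D_u", lower = 0)
  check_scalar(decay, "decay", lower = 0)
  check_scalar(u_cap, "u_cap", allow_inf = TRUE)
  if (u_cap <= 0) stop("`u_cap` must be positive (use Inf to disable)", call. = FALSE)
  stopifnot(is.logical(shared_noise), length(shared_noise) == 1L)

  courant <- D_u * dt / h^2
  if (courant > 0.25) {
    stop(
      "explicit diffusion unstable: D_u * dt / h^2 = ", signif(courant, 4),
      " exceeds 1/4; reduce dt or D_u",
      call. = FALSE
    )
  }

  structure(
    list(
      a = a, b = b, epsilon = epsilon, delta = delta, D = D, lam = lam,
      dt = dt, h = h, D_u = D_u, bc = bc, bc_code = bc_code(bc),
      decay = decay, u_cap = u_cap, shared_noise = shared_noise
    ),
    class = "camp_params"
  )
}

#' Noise-rate presets
#'
#' A noise cutoff frequency "of the order of" the excitability parameter
#' \eqn{\epsilon} admits two readings, so both limiting presets are
#' pre-wired for sensitivity analysis: `"slow"` sets
#' \eqn{\lambda = \epsilon} (quasi-static, quenched-like heterogeneity) and
#' `"fast"` sets \eqn{\lambda = 1/\epsilon} (white-noise-like). Neither
#' sustains the circular-wave regime at the calibrated kinetics — slow
#' noise never mean-reverts within a run and lets reactive cells grow
#' without bound, fast noise averages out before it can nucleate a
#' pacemaker — which is why the default `lam` in [model_params()] sits in
#' between.
#'
#' @param preset `"slow"` or `"fast"`.
#' @param epsilon Excitability parameter the rate is tied to.
#' @return The corresponding rate \eqn{\lambda}.
#' @examples
#' noise_preset("slow", 0.02)
#' noise_preset("fast", 0.02)
#' @export
noise_preset <- function(preset = c("slow", "fast"), epsilon = 0.02) {
  preset <- match.arg(preset)
  check_scalar(epsilon, "epsilon")
  if (preset == "slow") epsilon else 1 / epsilon
}

#' @export
print.camp_params <- function(x, ...) {
  cat("<camp_params>\n")
  cat(sprintf(
    "  kinetics: a = %g, b = %g, epsilon = %g, delta = %g\n",
    x$a, x$b, x$epsilon, x$delta
  ))
  cat(sprintf("  noise:    D = %g, lam = %g (corr. time %g)\n",
    x$D, x$lam, if (x$lam > 0) 1 / x$lam else Inf
  ))
  cat(sprintf(
    "  numerics: dt = %g, h = %g, D_u = %g, bc = %s, decay = %g\n",
    x$dt, x$h, x$D_u, x$bc, x$decay
  ))
  invisible(x)
}
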