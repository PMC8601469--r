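#' Spatial field statistics
#'
#' Statistics over *all* `N^2` lattice sites (occupied and empty alike, as
#' the extracellular cAMP field covers the whole medium):
#' `mean_field()` is \eqn{\bar u = N^{-2} \sum_{ij} u_{ij}},
#' `spatial_std()` is the population root-mean-square deviation
#' \eqn{\sigma = [N^{-2} \sum_{ij} (u_{ij} - \bar u)^2]^{1/2}}, and
#' `neighbor_covariance()` is the nearest-neighbor spatial auto-covariance
#' \deqn{Cov = N^{-2} \sum_{ij} \tfrac14 \sum_{b \in \mathcal{N}_{ij}}
#'   (u_{ij} - \bar u)(u_b - \bar u)}
#' over the four von Neumann neighbors, with edge lookups following the
#' same boundary convention as the simulator (mirrored for `"noflux"`,
#' wrapped for `"periodic"`).
#'
#' @param u Numeric matrix (a field snapshot).
#' @param bc Boundary convention for the neighbor lookup.
#' @return A single number.
#' @examples
#' u <- matrix(c(0, 0, 1, 1), 2, 2)
#' mean_field(u)
#' spatial_std(u)
#' @export
mean_field <- function(u) {
  stopifnot(is.matrix(u), is.numeric(u))
  if (length(u) == 0L) stop("empty grid", call. = FALSE)
  mean(u)
}

#' @rdname mean_field
#' @export
spatial_std <- function(u) {
  stopifnot(is.matrix(u), is.numeric(u))
  if (length(u) == 0L) stop("empty grid", call. = FALSE)
  sqrt(mean((u - mean(u))^2))
}

#' @rdname mean_field
#' @export
neighbor_covariance <- function(u, bc = c("noflux", "periodic")) {
  bc <- match.arg(bc)
  stopifnot(is.matrix(u), is.numeric(u))
  if (nrow(u) < 2L || ncol(u) < 2L) stop("grid must be at least 2 x 2", call. = FALSE)
  neighbor_cov_cpp(u, bc_code(bc))
}

as_series <- function(x) {
  if (inherits(x, "camp_trajectory")) {
    return(x$series)
  }
  stopifnot(is.data.frame(x))
  need <- c("iteration", "sigma")
  if (!all(need %in% names(x))) {
    stop("series needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  x
}

#' Synchrony index S
#'
#' Time average of the normalized nearest-neighbor covariance,
#' \eqn{S = \langle Cov(t) / \sigma^2(t) \rangle_t}. `S = 1` for a
#' completely synchronized (spatially smooth) network; a checkerboard
#' field gives `S = -1`. Iterations whose spatial variance does not exceed
#' `sigma_floor` are excluded (they carry no pattern and would divide by
#' ~0); by default the average runs over the oscillatory regime, i.e. all
#' iterations after the initial `n_head` growth phase.
#'
#' @param series A `camp_trajectory` or a data frame with columns
#'   `iteration`, `sigma`, `cov`.
#' @param window Optional integer vector of length 2, `c(first, last)`
#'   iteration (inclusive) to average over; overrides `n_head`.
#' @param n_head Number of initial growth-phase iterations excluded when
#'   `window` is `NULL` (default 300).
#' @param sigma_floor Variance floor below which an iteration is excluded.
#' @return The synchrony index, a single number `<= 1`.
#' @examples
#' s <- tibble::tibble(iteration = 1:10, sigma = 1, cov = 0.9)
#' synchrony_index(s, n_head = 0)
#' @export
synchrony_index <- function(series, window = NULL, n_head = 300L,
                            sigma_floor = 1e-12) {
  s <- as_series(series)
  if (!"cov" %in% names(s)) stop("series needs a `cov` column", call. = FALSE)
  if (is.null(window)) {
    keep <- s$iteration > n_head
  } else {
    stopifnot(length(window) == 2L)
    keep <- s$iteration >= window[1] & s$iteration <= window[2]
  }
  keep <- keep & s$sigma^2 > sigma_floor
  if (!any(keep)) {
    stop(
      "synchrony undefined: no iterations in the window have spatial ",
      "variance above sigma_floor (dead medium?)",
      call. = FALSE
    )
  }
  mean(s$cov[keep] / s$sigma[keep]^2)
}

#' Growth-phase fit, plateau level and crossover time of log sigma(t)
#'
#' The fluctuation width \eqn{\sigma(t)} of the cAMP field first grows
#' exponentially, then saturates and oscillates. `fit_growth_line()`
#' regresses \eqn{\log \sigma(t)} (natural log) on the iteration index over
#' the first `n_head` recorded iterations; `plateau_level()` is the mean of
#' \eqn{\log \sigma} over the last `n_tail` iterations; `crossover_time()`
#' intersects the two lines,
#' \eqn{T = (\mathrm{plateau} - \mathrm{intercept}) / \mathrm{slope}},
#' giving the iteration where the dynamics switch from growth to the
#' oscillatory regime. The log base rescales slope and intercept jointly,
#' so `T` is base-invariant.
#'
#' @param series A `camp_trajectory` or a data frame with `iteration` and
#'   `sigma` columns.
#' @param n_head Number of leading iterations in the growth fit
#'   (default 300).
#' @param n_tail Number of trailing iterations in the plateau mean
#'   (default 3000).
#' @return `fit_growth_line()`: a one-row tibble with `slope` (per
#'   iteration) and `intercept`; `plateau_level()`: a number;
#'   `crossover_time()`: the crossover iteration `T` (not necessarily an
#'   integer).
#' @examples
#' s <- tibble::tibble(iteration = 1:4000,
#'                     sigma = exp(pmin(-6 + 0.01 * (1:4000), -1)))
#' fit_growth_line(s)
#' crossover_time(s, n_tail = 3000)
#' @export
fit_growth_line <- function(series, n_head = 300L) {
  s <- as_series(series)
  check_scalar(n_head, "n_head", lower = 2, integerish = TRUE)
  if (nrow(s) < n_head) {
    stop("series has ", nrow(s), " iterations, need at least ", n_head,
      call. = FALSE
    )
  }
  head_s <- s[seq_len(n_head), ]
  if (any(head_s$sigma <= 0)) {
    stop(
      "sigma is 0 inside the growth window so log(sigma) is undefined; ",
      "seed more firing cells (larger f_fire) or shorten n_head",
      call. = FALSE
    )
  }
  fit <- lm(log(sigma) ~ iteration, data = head_s)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1])
  )
}

#' @rdname fit_growth_line
#' @export
plateau_level <- function(series, n_tail = 3000L) {
  s <- as_series(series)
  check_scalar(n_tail, "n_tail", lower = 1, integerish = TRUE)
  if (nrow(s) < n_tail) {
    stop("series has ", nrow(s), " iterations, need at least ", n_tail,
      call. = FALSE
    )
  }
  tail_s <- s$sigma[seq.int(nrow(s) - n_tail + 1L, nrow(s))]
  if (any(tail_s <= 0)) {
    stop("sigma is 0 inside the plateau window; the medium died",
      call. = FALSE
    )
  }
  mean(log(tail_s))
}

#' @rdname fit_growth_line
#' @export
crossover_time <- function(series, n_head = 300L, n_tail = 3000L) {
  s <- as_series(series)
  fit <- fit_growth_line(s, n_head = n_head)
  if (fit$slope <= 0) {
    stop(
      "no growth regime: the fitted log(sigma) slope is ",
      signif(fit$slope, 4), " <= 0",
      call. = FALSE
    )
  }
  plateau <- plateau_level(s, n_tail = n_tail)
  (plateau - fit$intercept) / fit$slope
}

#' Full trajectory summary
#'
#' Computes every headline statistic of a run in one tidy row: the
#' synchrony index `S`, the growth-line `slope` and `intercept`, the
#' `plateau` level of \eqn{\log\sigma}, the `crossover` iteration `T`, and
#' `ubar_osc`, the time average of the mean field \eqn{\bar u(t)} over the
#' oscillatory (post-crossover) window. Statistics whose preconditions fail
#' (e.g. no growth regime) are returned as `NA` rather than erroring, so
#' surveys never abort on a degenerate cell.
#'
#' `glance()` on a trajectory is an alias with the default windows.
#'
#' @param trajectory A `camp_trajectory` (or tidy series data frame).
#' @param n_head,n_tail Growth / plateau window lengths, as in
#'   [fit_growth_line()]; `n_tail` is truncated to half the series if the
#'   run is shorter than `2 * n_tail`.
#' @param sigma_floor Variance floor for the synchrony average.
#' @return A one-row tibble.
#' @examples
#' lat <- generate_lattice(32, 0.5, 0, seed = 1)
#' tr <- simulate_population(lat, model_params(), n_iter = 400, seed = 1,
#'                           record_fields = FALSE)
#' analyze_trajectory(tr, n_head = 100, n_tail = 100)
#' @export
analyze_trajectory <- function(trajectory, n_head = 300L, n_tail = 3000L,
                               sigma_floor = 1e-12) {
  s <- as_series(trajectory)
  n_tail <- min(n_tail, nrow(s) %/% 2L)
  maybe <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  fit <- tryCatch(fit_growth_line(s, n_head = n_head),
    error = function(e) tibble::tibble(slope = NA_real_, intercept = NA_real_)
  )
  plateau <- maybe(plateau_level(s, n_tail = n_tail))
  crossover <- maybe(crossover_time(s, n_head = n_head, n_tail = n_tail))
  S <- maybe(synchrony_index(s, n_head = n_head, sigma_floor = sigma_floor))

  osc_from <- if (is.finite(crossover)) max(n_head, ceiling(crossover)) else n_head
  osc <- s$iteration > osc_from
  ubar_osc <- if ("ubar" %in% names(s) && any(osc)) mean(s$ubar[osc]) else NA_real_

  tibble::tibble(
    S = S, slope = fit$slope, intercept = fit$intercept,
    plateau = plateau, crossover = crossover, ubar_osc = ubar_osc,
    n_iter = nrow(s)
  )
}

#' @describeIn analyze_trajectory broom-style one-row summary of a
#'   trajectory.
#' @param x A `camp_trajectory`.
#' @param ... Passed to `analyze_trajectory()`.
#' @method glance camp_trajectory
#' @export
glance.camp_trajectory <- function(x, ...) {
  res <- analyze_trajectory(x, ...)
  tibble::tibble(
    N = x$lattice$N, phi1 = x$lattice$phi1, phi2 = x$lattice$phi2,
    seed = x$seed, res
  )
}

#' Kymograph: square-root activator level along one lattice row over time
#'
#' Extracts the space-time matrix of \eqn{\sqrt{u}} along the recorded
#' lattice row for the last `last_n` iterations of a run (tiny negative
#' round-off values of `u` are clipped to 0 before the square root). Bright
#' diagonal stripes are travelling wave fronts; their slope is the front
#' speed.
#'
#' @param trajectory A `camp_trajectory`.
#' @param row Lattice row (1-based). Must equal the row recorded during the
#'   run (`kymo_row`, the middle row by default).
#' @param last_n Number of trailing iterations shown (default 2000).
#' @return A `camp_kymograph`: a `last_n x N` matrix of \eqn{\sqrt{u}} with
#'   an `iterations` attribute; plot with [autoplot()].
#' @export
kymograph <- function(trajectory, row = NULL, last_n = 2000L) {
  stopifnot(inherits(trajectory, "camp_trajectory"))
  check_scalar(last_n, "last_n", lower = 1, integerish = TRUE)
  if (is.null(row)) row <- trajectory$kymo_row
  check_scalar(row, "row", lower = 1, upper = trajectory$lattice$N,
    integerish = TRUE
  )
  if (row != trajectory$kymo_row) {
    stop(
      "row ", row, " was not recorded (the run recorded row ",
      trajectory$kymo_row, "); re-run simulate_population(kymo_row = ", row, ")",
      call. = FALSE
    )
  }
  n <- nrow(trajectory$midrow)
  if (last_n > n) {
    stop("trajectory has only ", n, " iterations, cannot take last ", last_n,
      call. = FALSE
    )
  }
  idx <- seq.int(n - last_n + 1L, n)
  m <- sqrt(pmax(trajectory$midrow[idx, , drop = FALSE], 0))
  structure(m,
    iterations = trajectory$series$iteration[idx],
    row = row, class = c("camp_kymograph", "matrix")
  )
}
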