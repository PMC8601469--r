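#' Local phase of the activator-recovery excursion
#'
#' Maps each site to the angle \eqn{\theta_{ij} = \mathrm{atan2}(v -
#' v_{ref},\, u - u_{ref})} of its `(u, v)` point around a reference point
#' chosen strictly inside the excursion loop of the local dynamics. A
#' rotating spiral core is a *phase singularity*: a point around which
#' \eqn{\theta} winds by \eqn{\pm 2\pi}. Target (circular) waves produce
#' closed level sets of `u` but no singularity, which is why tip detection
#' works on the `(u, v)` phase rather than on `u` alone.
#'
#' This layer is a transparent heuristic operationalization of a
#' classification that is otherwise done by eye; its labels are advisory.
#'
#' @param u,v Field matrices of equal dimensions.
#' @param u_ref,v_ref Reference point inside the excursion loop. The
#'   defaults sit between the rest state at the origin and the excited
#'   plateau `u = 1`.
#' @return Matrix of angles in `(-pi, pi]`.
#' @examples
#' phase_field(matrix(1.5, 2, 2), matrix(0.15, 2, 2))[1, 1] # 0
#' @export
phase_field <- function(u, v, u_ref = 0.5, v_ref = 0.15) {
  stopifnot(is.matrix(u), is.matrix(v), all(dim(u) == dim(v)))
  atan2(v - v_ref, u - u_ref)
}

wrap_angle <- function(x) {
  x - 2 * pi * round(x / (2 * pi))
}

# Box blur with edge replication; radius 0 is the identity.  Used to
# suppress site-scale noise before phase/tip analysis.
smooth_field <- function(m, radius = 1L) {
  if (radius < 1L) return(m)
  n1 <- nrow(m)
  n2 <- ncol(m)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, n1, n2)
  w <- 0L
  for (di in -radius:radius) {
    for (dj in -radius:radius) {
      out <- out + m[pad(seq_len(n1) + di, n1), pad(seq_len(n2) + dj, n2)]
      w <- w + 1L
    }
  }
  out / w
}

#' Locate and count phase singularities (spiral tips)
#'
#' Computes the winding number of the phase around every 2x2 plaquette of
#' the grid: the four wrapped phase differences around the loop sum to
#' \eqn{\pm 2\pi} at a singularity and to 0 elsewhere.
#' `phase_singularities()` returns one row per tip with its plaquette
#' corner and topological charge; `count_phase_singularities()` returns
#' just the count.
#'
#' @param theta Angle matrix (from [phase_field()]).
#' @return `phase_singularities()`: tibble with columns `row`, `col`
#'   (upper-left plaquette corner, 1-based) and `charge` (+1 or -1).
#'   `count_phase_singularities()`: a non-negative integer.
#' @examples
#' N <- 21
#' sp <- outer(1:N, 1:N, function(i, j) atan2(j - 11, i - 11))
#' count_phase_singularities(sp)
#' @export
phase_singularities <- function(theta) {
  stopifnot(is.matrix(theta), is.numeric(theta))
  nr <- nrow(theta)
  nc <- ncol(theta)
  if (nr < 2L || nc < 2L) {
    return(tibble::tibble(row = integer(), col = integer(), charge = integer()))
  }
  a <- theta[-nr, -nc] # (i, j)
  b <- theta[-1, -nc]  # (i+1, j)
  c_ <- theta[-1, -1]  # (i+1, j+1)
  d <- theta[-nr, -1]  # (i, j+1)
  wind <- wrap_angle(b - a) + wrap_angle(c_ - b) +
    wrap_angle(d - c_) + wrap_angle(a - d)
  charge <- round(wind / (2 * pi))
  hit <- which(charge != 0, arr.ind = TRUE)
  tibble::tibble(
    row = as.integer(hit[, 1]), col = as.integer(hit[, 2]),
    charge = as.integer(charge[charge != 0])
  )
}

#' @rdname phase_singularities
#' @export
count_phase_singularities <- function(theta) {
  nrow(phase_singularities(theta))
}

#' Classify the wave pattern of a trajectory
#'
#' Advisory circular/spiral/none labelling of a run, operationalizing what
#' is otherwise judged from snapshots by eye. The rule: if the late-time
#' plateau of the fluctuation width \eqn{\sigma} stays below
#' `activity_floor` the medium is dead (`"NONE"`); otherwise spiral tips
#' (phase singularities) are counted on every snapshot in the window, and
#' the run is `"SPIRAL"` when tips persist in at least `spiral_frac` of the
#' snapshots, `"CIRCULAR"` when they appear in fewer than `circular_frac`
#' (waves without singularities are target waves), and `"NOISY"` in
#' between. All thresholds are configurable and the label is advisory,
#' never a hard gate.
#'
#' @param trajectory A `camp_trajectory` with field snapshots.
#' @param window Iteration range `c(first, last)` of snapshots to use;
#'   default all snapshots after the first 300 iterations (falling back to
#'   all snapshots for short runs).
#' @param activity_floor Floor on the time-averaged \eqn{\sigma} in the
#'   window below which the run counts as waveless.
#' @param spiral_frac,circular_frac Sustained-tip fraction thresholds of
#'   the decision rule.
#' @param u_ref,v_ref Phase reference point, see [phase_field()].
#' @param smooth_radius Box-blur radius (sites) applied to the `u`/`v`
#'   snapshots before the phase is taken; suppresses site-scale noise that
#'   would otherwise read as spurious singularity pairs. 0 disables.
#' @param amp_floor Minimum `(u, v)` excursion amplitude (distance from the
#'   reference point, after smoothing) required at all four corners of a
#'   plaquette for a detected singularity to count as a genuine spiral tip;
#'   in low-amplitude regions the phase is numerically meaningless.
#' @return A `camp_pattern` report: list with the per-snapshot tibble
#'   `tips` (`iteration`, `n_tips`, `net_charge`), `tip_fraction`,
#'   `wave_activity`, `sigma_plateau` and `label`.
#' @examples
#' lat <- generate_lattice(32, 0.5, 0, seed = 1)
#' tr <- simulate_population(lat, model_params(), n_iter = 120, seed = 1,
#'                           record_every = 30)
#' classify_pattern(tr, window = c(1, 120))$label
#' @export
classify_pattern <- function(trajectory, window = NULL,
                             activity_floor = 1e-3, spiral_frac = 0.5,
                             circular_frac = 0.1, u_ref = 0.5,
                             v_ref = 0.15, smooth_radius = 2L,
                             amp_floor = 0.05) {
  stopifnot(inherits(trajectory, "camp_trajectory"))
  iters <- trajectory$snapshots$iterations
  if (length(iters) == 0L) {
    stop("trajectory has no field snapshots (record_fields = FALSE?)",
      call. = FALSE
    )
  }
  if (is.null(window)) {
    window <- c(min(300L, max(iters)), max(iters))
  }
  stopifnot(length(window) == 2L)
  sel <- which(iters >= window[1] & iters <= window[2])
  if (length(sel) == 0L) stop("no snapshots inside the window", call. = FALSE)

  tips <- purrr::map_dfr(sel, function(k) {
    u <- smooth_field(trajectory$snapshots$u[[k]], smooth_radius)
    v <- smooth_field(trajectory$snapshots$v[[k]], smooth_radius)
    th <- phase_field(u, v, u_ref = u_ref, v_ref = v_ref)
    ps <- phase_singularities(th)
    if (nrow(ps) > 0 && amp_floor > 0) {
      amp <- sqrt((u - u_ref)^2 + (v - v_ref)^2)
      keep <- vapply(seq_len(nrow(ps)), function(r) {
        i <- ps$row[r]
        j <- ps$col[r]
        min(amp[i:(i + 1), j:(j + 1)]) >= amp_floor
      }, logical(1))
      ps <- ps[keep, ]
    }
    tibble::tibble(
      iteration = iters[k], n_tips = nrow(ps),
      net_charge = if (nrow(ps)) sum(ps$charge) else 0L
    )
  })

  s <- trajectory$series
  in_win <- s$iteration >= window[1] & s$iteration <= window[2]
  sigma_plateau <- mean(s$sigma[in_win])
  wave_activity <- is.finite(sigma_plateau) && sigma_plateau > activity_floor
  tip_fraction <- mean(tips$n_tips > 0)

  label <- if (!wave_activity) {
    "NONE"
  } else if (tip_fraction >= spiral_frac) {
    "SPIRAL"
  } else if (tip_fraction < circular_frac) {
    "CIRCULAR"
  } else {
    "NOISY"
  }

  structure(
    list(
      tips = tips, tip_fraction = tip_fraction,
      wave_activity = wave_activity, sigma_plateau = sigma_plateau,
      label = label, window = window,
      thresholds = list(
        activity_floor = activity_floor, spiral_frac = spiral_frac,
        circular_frac = circular_frac
      )
    ),
    class = "camp_pattern"
  )
}

#' @export
print.camp_pattern <- function(x, ...) {
  cat(sprintf(
    "<camp_pattern> label = %s (tip fraction %.2f over %d snapshots, sigma plateau %.3g)\n",
    x$label, x$tip_fraction, nrow(x$tips), x$sigma_plateau
  ))
  invisible(x)
}

#' @describeIn classify_pattern Per-snapshot tip counts as a tibble.
#' @param x A `camp_pattern`.
#' @param ... Unused.
#' @method tidy camp_pattern
#' @export
tidy.camp_pattern <- function(x, ...) {
  x$tips
}
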