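# Explicit-loop reference implementations used as independent oracles.
# Deliberately naive: correctness over speed.

mirror_idx <- function(i, n) min(max(i, 1L), n)
wrap_idx <- function(i, n) ((i - 1L) %% n) + 1L

bf_mean <- function(u) {
  s <- 0
  for (i in seq_len(nrow(u))) for (j in seq_len(ncol(u))) s <- s + u[i, j]
  s / (nrow(u) * ncol(u))
}

bf_std <- function(u) {
  m <- bf_mean(u)
  s <- 0
  for (i in seq_len(nrow(u))) for (j in seq_len(ncol(u))) s <- s + (u[i, j] - m)^2
  sqrt(s / (nrow(u) * ncol(u)))
}

bf_neighbor_cov <- function(u, bc = "noflux") {
  n1 <- nrow(u); n2 <- ncol(u)
  idx <- if (bc == "periodic") wrap_idx else mirror_idx
  m <- bf_mean(u)
  acc <- 0
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      nbrs <- c(
        u[idx(i - 1L, n1), j], u[idx(i + 1L, n1), j],
        u[i, idx(j - 1L, n2)], u[i, idx(j + 1L, n2)]
      )
      for (b in nbrs) acc <- acc + 0.25 * (u[i, j] - m) * (b - m)
    }
  }
  acc / (n1 * n2)
}

bf_laplacian <- function(f, bc = "noflux", h = 1) {
  n1 <- nrow(f); n2 <- ncol(f)
  idx <- if (bc == "periodic") wrap_idx else mirror_idx
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      out[i, j] <- (f[idx(i - 1L, n1), j] + f[idx(i + 1L, n1), j] +
        f[i, idx(j - 1L, n2)] + f[i, idx(j + 1L, n2)] - 4 * f[i, j]) / h^2
    }
  }
  out
}

# A hand-built lattice (bypassing the random generator) for targeted
# dynamics tests: `types` is an N x N integer matrix of 0/1/2 codes.
manual_lattice <- function(types) {
  structure(
    list(
      N = nrow(types), phi1 = mean(types != 0L), phi2 = NA_real_,
      seed = 0L, type_map = types
    ),
    class = "camp_lattice"
  )
}

manual_state <- function(u, v = NULL, eta = NULL) {
  z <- matrix(0, nrow(u), ncol(u))
  structure(
    list(u = u, v = if (is.null(v)) z else v,
         eta = if (is.null(eta)) z else eta, iteration = 0L),
    class = "camp_state"
  )
}

# Minimal hand-built trajectory carrying prescribed snapshots, for testing
# the pattern classifier on synthetic fields.
manual_trajectory <- function(us, vs, iterations, bc = "noflux") {
  sigma <- vapply(us, spatial_std, numeric(1))
  structure(
    list(
      series = tibble::tibble(
        iteration = iterations,
        ubar = vapply(us, mean_field, numeric(1)),
        sigma = sigma,
        cov = vapply(us, neighbor_covariance, numeric(1), bc = bc)
      ),
      midrow = do.call(rbind, lapply(us, function(u) u[nrow(u) %/% 2L, ])),
      kymo_row = nrow(us[[1]]) %/% 2L,
      snapshots = list(u = us, v = vs, iterations = iterations),
      state = manual_state(us[[length(us)]]),
      lattice = manual_lattice(matrix(1L, nrow(us[[1]]), ncol(us[[1]]))),
      params = model_params(), seed = 0L,
      n_iter = max(iterations), record_every = 1L
    ),
    class = "camp_trajectory"
  )
}
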