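test_that("field statistics match explicit-loop oracles on small random grids", {
  set.seed(20)
  for (n in c(2L, 5L, 8L)) {
    u <- matrix(rnorm(n * n), n, n)
    expect_equal(mean_field(u), bf_mean(u), tolerance = 1e-12)
    expect_equal(spatial_std(u), bf_std(u), tolerance = 1e-12)
    for (bc in c("noflux", "periodic")) {
      expect_equal(neighbor_covariance(u, bc = bc),
        bf_neighbor_cov(u, bc = bc),
        tolerance = 1e-12
      )
    }
  }
})

test_that("hand-computable grids give the expected statistics", {
  u <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(mean_field(u), 0.5)
  expect_equal(spatial_std(u), 0.5)
  expect_equal(mean_field(matrix(4.2, 3, 3)), 4.2)
  expect_equal(spatial_std(matrix(4.2, 3, 3)), 0)
  expect_equal(neighbor_covariance(matrix(1, 4, 4)), 0)
  # perfect +-1 checkerboard under periodic wraparound: every neighbor
  # product is -1 and the variance is 1
  cb <- outer(1:6, 1:6, function(i, j) (-1)^(i + j))
  expect_equal(neighbor_covariance(cb, bc = "periodic"), -1)
  expect_equal(spatial_std(cb), 1)
})

test_that("the recorded series agrees with statistics recomputed from snapshots", {
  lat <- generate_lattice(24, 0.5, 0.2, seed = 21)
  tr <- simulate_population(lat, model_params(), n_iter = 90, seed = 21,
    record_every = 30
  )
  for (k in seq_along(tr$snapshots$iterations)) {
    u <- tr$snapshots$u[[k]]
    row <- tr$series[tr$series$iteration == tr$snapshots$iterations[k], ]
    expect_equal(row$ubar, mean_field(u), tolerance = 1e-12)
    expect_equal(row$sigma, spatial_std(u), tolerance = 1e-12)
    expect_equal(row$cov, neighbor_covariance(u, bc = "noflux"), tolerance = 1e-10)
  }
})

test_that("the synchrony index behaves at its analytic limits", {
  # a smooth long-wavelength field is almost perfectly synchronized
  N <- 64
  smooth <- outer(1:N, 1:N, function(i, j) sin(2 * pi * (i + j) / N))
  s_smooth <- tibble::tibble(
    iteration = 1:5, ubar = mean_field(smooth),
    sigma = spatial_std(smooth),
    cov = neighbor_covariance(smooth, bc = "periodic")
  )
  expect_gt(synchrony_index(s_smooth, n_head = 0), 0.99)
  expect_lte(synchrony_index(s_smooth, n_head = 0), 1)

  # a checkerboard at every recorded time gives exactly -1
  cb <- outer(1:8, 1:8, function(i, j) (-1)^(i + j))
  s_cb <- tibble::tibble(
    iteration = 1:10, ubar = 0, sigma = spatial_std(cb),
    cov = neighbor_covariance(cb, bc = "periodic")
  )
  expect_equal(synchrony_index(s_cb, n_head = 0), -1)

  # a dead medium has no defined synchrony
  dead <- tibble::tibble(iteration = 1:10, sigma = 0, cov = 0)
  expect_error(synchrony_index(dead, n_head = 0), "undefined")

  # window selection and the growth-phase exclusion
  s_mix <- tibble::tibble(
    iteration = 1:400,
    sigma = 1,
    cov = c(rep(0, 300), rep(0.9, 100))
  )
  expect_equal(synchrony_index(s_mix), 0.9)
  expect_equal(synchrony_index(s_mix, window = c(1, 300)), 0)
})

test_that("normalized neighbor covariance stays within [-1, 1] on real runs", {
  lat <- generate_lattice(48, 0.6, 0.2, seed = 22)
  tr <- simulate_population(lat, model_params(), n_iter = 800, seed = 22,
    record_fields = FALSE
  )
  s <- tr$series[tr$series$sigma^2 > 1e-12, ]
  r <- s$cov / s$sigma^2
  expect_true(all(r <= 1 + 1e-9))
  expect_true(all(r >= -1 - 1e-9))
})

test_that("growth-line fitting recovers exact and noisy exponential heads", {
  it <- 1:1000
  exact <- tibble::tibble(iteration = it, sigma = exp(-6 + 0.01 * it))
  fit <- fit_growth_line(exact, n_head = 300)
  expect_equal(fit$slope, 0.01, tolerance = 1e-10)
  expect_equal(fit$intercept, -6, tolerance = 1e-8)

  set.seed(23)
  noisy <- tibble::tibble(
    iteration = it,
    sigma = exp(-6 + 0.01 * it + rnorm(1000, 0, 0.05))
  )
  nf <- fit_growth_line(noisy, n_head = 300)
  fit_lm <- lm(log(sigma) ~ iteration, data = noisy[1:300, ])
  expect_equal(nf$slope, unname(coef(fit_lm)[2]))
  se <- summary(fit_lm)$coefficients[2, 2]
  expect_lt(abs(nf$slope - 0.01), 3 * se)

  flat <- tibble::tibble(iteration = it, sigma = rep(exp(-2), 1000))
  expect_equal(fit_growth_line(flat, n_head = 300)$slope, 0)

  withzero <- tibble::tibble(iteration = it, sigma = c(0, exp(-6 + 0.01 * it[-1])))
  expect_error(fit_growth_line(withzero), "firing")
  expect_error(fit_growth_line(exact[1:100, ], n_head = 300), "at least")
})

test_that("the plateau level is the mean of the trailing log sigma window", {
  s <- tibble::tibble(iteration = 1:4000, sigma = exp(-1.5))
  expect_equal(plateau_level(s), -1.5)
  set.seed(24)
  wob <- tibble::tibble(
    iteration = 1:4000,
    sigma = exp(-1.5 + c(rep(1, 1000), rnorm(3000, 0, 0.1)))
  )
  expect_equal(plateau_level(wob, n_tail = 3000), -1.5, tolerance = 3 * 0.1 / sqrt(3000))
  expect_equal(plateau_level(s, n_tail = 4000), -1.5) # whole series
  expect_error(plateau_level(s[1:100, ]), "at least")
})

test_that("the crossover time is the intersection of the two regime lines", {
  it <- 1:4000
  two_regime <- tibble::tibble(
    iteration = it,
    sigma = exp(pmin(-6 + 0.01 * it, -1))
  )
  expect_equal(crossover_time(two_regime), 500, tolerance = 1)
  # plateau equal to the head line at t = 0 crosses immediately
  flat0 <- tibble::tibble(
    iteration = it,
    sigma = exp(c(-6 + 0.01 * (1:300), rep(-6, 3700)))
  )
  expect_lt(abs(crossover_time(flat0, n_tail = 3000)), 65)
  declining <- tibble::tibble(iteration = it, sigma = exp(-0.01 * it))
  expect_error(crossover_time(declining), "no growth regime")
})

test_that("crossover recovery is exact on constructed breaks of varying position", {
  for (brk in c(400, 800, 1500)) {
    it <- 1:5000
    s <- tibble::tibble(
      iteration = it,
      sigma = exp(pmin(-7 + 0.008 * it, -7 + 0.008 * brk))
    )
    expect_equal(crossover_time(s, n_head = 300, n_tail = 3000),
      brk,
      tolerance = 1
    )
  }
})

test_that("kymographs extract sqrt(u) along the recorded row", {
  lat <- generate_lattice(24, 0.5, 0, seed = 25)
  tr <- simulate_population(lat, model_params(), n_iter = 120, seed = 25,
    record_fields = FALSE
  )
  ky <- kymograph(tr, last_n = 50)
  expect_identical(dim(unclass(ky)), c(50L, 24L))
  expect_identical(
    as.vector(ky[50, ]),
    as.vector(sqrt(pmax(tr$midrow[120, ], 0)))
  )
  expect_identical(attr(ky, "iterations"), 71:120)
  # tiny negative round-off is clipped, never NaN
  tr$midrow[120, 1] <- -1e-15
  expect_identical(kymograph(tr, last_n = 1)[1, 1], 0)
  expect_false(anyNA(kymograph(tr, last_n = 120)))
  expect_error(kymograph(tr, last_n = 121), "only 120")
  expect_error(kymograph(tr, row = 2), "not recorded")
  expect_error(kymograph(tr, row = 99), "in \\[1, 24\\]")
})

test_that("an all-zero trajectory yields an all-zero kymograph", {
  lat <- generate_lattice(16, 0.5, 0, seed = 26)
  tr <- simulate_population(lat, model_params(D = 0),
    n_iter = 40, seed = 26,
    f_fire = 0, record_fields = FALSE
  )
  expect_true(all(kymograph(tr, last_n = 40) == 0))
})

test_that("trajectory summaries are tidy and survive degenerate runs", {
  lat <- generate_lattice(32, 0.5, 0.1, seed = 27)
  tr <- simulate_population(lat, model_params(), n_iter = 400, seed = 27,
    record_fields = FALSE
  )
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "ubar", "sigma", "cov"))
  g <- glance(tr, n_head = 100, n_tail = 100)
  expect_identical(nrow(g), 1L)
  expect_identical(g$phi2, 0.1)
  # a dead medium reports NA statistics instead of erroring
  dead <- simulate_population(lat, model_params(D = 0),
    n_iter = 400,
    seed = 27, f_fire = 0, record_fields = FALSE
  )
  gd <- analyze_trajectory(dead, n_head = 100, n_tail = 100)
  expect_true(is.na(gd$S) && is.na(gd$slope))
})
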