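# exact-sampling helper: pooled dataset from a harmonic ladder
ladder_dataset <- function(springs, n_per_state, seed, centers = NULL) {
  set.seed(seed)
  K <- length(springs)
  if (is.null(centers)) centers <- rep(0, K)
  xs <- unlist(lapply(seq_len(K), function(k) {
    rnorm(n_per_state, centers[k], 1 / sqrt(springs[k]))
  }))
  u_kn <- do.call(rbind, lapply(seq_len(K), function(l) {
    0.5 * springs[l] * (xs - centers[l])^2
  }))
  reduced_potential_dataset(
    u_kn, rep(n_per_state, K),
    origin_state = rep(seq_len(K), each = n_per_state)
  )
}

test_that("MBAR handles degenerate and symmetric cases", {
  expect_equal(mbar_solve(matrix(rnorm(10), 1, 10), n_k = 10), 0)
  # two identical states: delta f within 3 bootstrap sigma of 0
  ds <- ladder_dataset(c(2, 2), 2000, seed = 5)
  f <- mbar_solve(ds)
  bt <- bootstrap_delta_g(ds, n_boot = 100, seed = 5)
  expect_lte(abs(f[2]), 3 * bt$sigma + 1e-12)
  expect_error(
    mbar_solve(reduced_potential_dataset(
      matrix(0, 2, 4), c(4, 0)
    )),
    "contribute"
  )
})

test_that("MBAR recovers the analytic harmonic free energy ladder", {
  # springs 1 and 4 at beta = 1: delta f = log(4)/2
  ds <- ladder_dataset(c(1, 4), 5000, seed = 11)
  f <- mbar_solve(ds)
  bt <- bootstrap_delta_g(ds, n_boot = 100, seed = 11)
  expect_lt(abs(f[2] - 0.5 * log(4)), 3 * bt$sigma)
  # multi-state ladders K in {5, 8}
  for (K in c(5, 8)) {
    springs <- 2^(seq_len(K) - 1)
    ds <- ladder_dataset(springs, 2000, seed = K)
    f <- mbar_solve(ds)
    exact <- 0.5 * log(springs) - 0.5 * log(springs[1])
    bt <- bootstrap_delta_g(ds, n_boot = 80, seed = K)
    expect_lt(abs(f[K] - exact[K]), 3 * bt$sigma)
  }
})

test_that("MBAR on two states agrees with an independent BAR solver", {
  ds <- ladder_dataset(c(1, 4), 3000, seed = 3)
  f <- mbar_solve(ds, tol = 1e-12)
  n <- 3000
  w_f <- ds$u_kn[2, 1:n] - ds$u_kn[1, 1:n]
  w_r <- ds$u_kn[1, n + 1:n] - ds$u_kn[2, n + 1:n]
  expect_equal(f[2], oracle_bar(w_f, w_r), tolerance = 1e-8)
})

test_that("MBAR is invariant to shifting a state's potential by a constant", {
  ds <- ladder_dataset(c(1, 4), 1000, seed = 2)
  f <- mbar_solve(ds)
  shifted <- ds
  shifted$u_kn[2, ] <- shifted$u_kn[2, ] + 7.5
  f2 <- mbar_solve(shifted)
  expect_equal(f2[2] - 7.5, f[2], tolerance = 1e-8)
})

test_that("decorrelation subsampling strides by ceil(g)", {
  expect_equal(subsample_decorrelated(1:10, 1), 1:10)
  expect_equal(subsample_decorrelated(1:10, 2.4), c(1, 4, 7, 10))
  m <- matrix(1:20, 2, 10)
  expect_equal(subsample_decorrelated(m, 2.4), m[, c(1, 4, 7, 10)])
  expect_error(subsample_decorrelated(1:10, 10), "fewer than 2")
})

test_that("bootstrap uncertainty scales as expected", {
  ds <- ladder_dataset(c(1, 4), 800, seed = 8)
  bt <- bootstrap_delta_g(ds, n_boot = 150, seed = 1)
  # duplicating every sample (treated as independent) shrinks sigma ~1/sqrt(2)
  dup <- reduced_potential_dataset(
    ds$u_kn[, rep(seq_len(ncol(ds$u_kn)), 2)],
    ds$n_k * 2,
    origin_state = rep(ds$origin_state, 2)
  )
  bt2 <- bootstrap_delta_g(dup, n_boot = 150, seed = 1)
  ratio <- bt2$sigma / bt$sigma
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 0.92)
  # zero-variance degenerate dataset: sigma exactly 0
  flat <- reduced_potential_dataset(
    matrix(rep(c(0.3, 0.7), 10), 2, 10), c(5, 5),
    origin_state = rep(1:2, each = 5)
  )
  bt3 <- bootstrap_delta_g(flat, n_boot = 30, seed = 2)
  expect_equal(bt3$sigma, 0)
})

test_that("delta-G time series: prefix growth, exact final point, drift detection", {
  arc <- make_harmonic_archive(400, springs = c(1, 4), seed = 21)
  ts <- delta_g_time_series(arc, n_points = 10, n_boot = 20)
  expect_equal(nrow(ts), 10)
  full <- estimate_free_energy(arc, n_boot = 0)
  expect_identical(ts$delta_g[10], full$delta_g) # prefix property, bit-exact
  # stationary archive: trailing slope flat at the toy-unit threshold
  sl <- slope_last_window(ts)
  expect_true(convergence_verdict(sl$slope, sl$two_se, threshold = 0.001))
  # planted slow equilibration: state 2 sampled off-center until 65% of
  # the run; early points differ from the final estimate and the
  # trailing slope is significantly nonzero
  drift <- make_harmonic_archive(
    400, c(1, 4),
    centers2 = c(rep(1.5, 260), rep(0, 140)), seed = 22
  )
  ts2 <- delta_g_time_series(drift, n_points = 10, n_boot = 20)
  expect_gt(
    abs(ts2$delta_g[4] - ts2$delta_g[10]),
    2 * sqrt(ts2$sigma[4]^2 + ts2$sigma[10]^2)
  )
  sl2 <- slope_last_window(ts2)
  expect_false(convergence_verdict(sl2$slope, sl2$two_se, threshold = 0.001))
  # truncation to one point reproduces that prefix estimate
  one <- delta_g_time_series(arc, n_points = 1, n_boot = 0)
  expect_equal(nrow(one), 1)
  expect_identical(one$delta_g, full$delta_g)
})

test_that("trailing-window slope is OLS with honest uncertainty", {
  series <- tibble::tibble(iteration = 1:10, delta_g = 0.3 * (1:10))
  sl <- slope_last_window(series, window_fraction = 1)
  expect_equal(sl$slope, 0.3, tolerance = 1e-12)
  expect_lt(sl$two_se, 1e-10)
  flat <- tibble::tibble(iteration = 1:10, delta_g = rep(1.2, 10))
  expect_equal(slope_last_window(flat)$slope, 0, tolerance = 1e-12)
  expect_error(slope_last_window(series, span = 50), "longer")
  # white-noise series: mean estimated slope SE tracks the closed form
  set.seed(33)
  n <- 20
  sigma <- 0.5
  t <- 1:n
  se_closed <- sigma / sqrt(sum((t - mean(t))^2))
  ses <- replicate(300, {
    s <- tibble::tibble(iteration = t, delta_g = rnorm(n, sd = sigma))
    slope_last_window(s, window_fraction = 1)$two_se / 2
  })
  expect_lt(abs(mean(ses) / se_closed - 1), 0.2)
})

test_that("phase combination obeys quadrature and antisymmetry", {
  mk <- function(dg, sig) {
    structure(
      list(
        f_k = c(0, dg), delta_g = dg,
        delta_g_kcal_mol = kt_to_kcal(dg), sigma = sig,
        sigma_kcal_mol = kt_to_kcal(sig),
        ci95 = dg + c(-1.96, 1.96) * sig, n_bootstrap = 0,
        n_effective = 100, temperature = 300
      ),
      class = "free_energy_estimate"
    )
  }
  apo <- mk(-1.0, 0.1)
  cplx <- mk(-3.0, 0.1)
  dd <- combine_ddg(apo, cplx)
  expect_equal(dd$ddg, -2.0)
  expect_equal(dd$sigma, sqrt(0.02), tolerance = 1e-12)
  expect_equal(combine_ddg(apo, apo)$ddg, 0)
  expect_equal(combine_ddg(cplx, apo)$ddg, -dd$ddg)
})

test_that("tidy and glance views expose the estimate", {
  ds <- ladder_dataset(c(1, 4), 500, seed = 4)
  est <- estimate_free_energy(ds, n_boot = 40, seed = 4)
  td <- tidy(est)
  expect_equal(nrow(td), 2)
  expect_equal(td$f[1], 0)
  gl <- glance(est)
  expect_true(all(c("delta_g", "sigma", "ci95_lo", "n_effective")
  %in% names(gl)))
})
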