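test_that("statistical inefficiency matches white-noise and AR(1) theory", {
  set.seed(1)
  g_wn <- statistical_inefficiency(rnorm(10000))$g
  expect_lt(abs(g_wn - 1), 0.1)
  # AR(1): g = (1 + phi) / (1 - phi)
  for (phi in c(0.5, 0.9)) {
    x <- as.numeric(arima.sim(list(ar = phi), n = 1e5))
    g <- statistical_inefficiency(x)$g
    expect_lt(abs(g - (1 + phi) / (1 - phi)) / ((1 + phi) / (1 - phi)), 0.25)
  }
  # g_time carries the sampling interval (the "0.1 ns" convention)
  si <- statistical_inefficiency(rnorm(500), sampling_interval = 0.1)
  expect_equal(si$g_time, si$g * 0.1)
  expect_equal(si$g, 2 * si$tau + 1)
  expect_error(statistical_inefficiency(rep(1, 100)), "constant")
  expect_error(statistical_inefficiency(c(1, 2)), "short")
})

test_that("PCC handles exact, null, and degenerate relationships", {
  x <- rnorm(200)
  expect_equal(pcc_with_ci(x, x)$pcc, 1)
  expect_equal(pcc_with_ci(x, -2 * x + 7)$pcc, -1)
  expect_error(pcc_with_ci(x, rep(0, 200)), "variance")
  expect_error(pcc_with_ci(x, rnorm(100)), "aligned")
  # independent white noise: small r, CI covers 0 at near-nominal rate
  set.seed(5)
  cover <- replicate(100, {
    a <- rnorm(1000)
    b <- rnorm(1000)
    r <- pcc_with_ci(a, b)
    abs(r$pcc) < 0.1 && r$ci95[1] <= 0 && r$ci95[2] >= 0
  })
  expect_gte(mean(cover), 0.9)
})

test_that("replica averaging uses the Fisher-z mean", {
  set.seed(9)
  n <- 400
  x <- rnorm(n)
  # identical replicas collapse to the single-replica value
  du <- cbind(x, x, x)
  y <- 0.7 * x + rnorm(n, sd = 0.5)
  dof <- cbind(y, y, y)
  single <- pcc_with_ci(x, y)
  multi <- replica_averaged_pcc(du, dof)
  expect_equal(multi$pcc, single$pcc, tolerance = 1e-12)
  expect_equal(multi$per_replica_pccs, rep(single$pcc, 3))
  # z-symmetric pair (+r, -r) combines to ~0
  y2 <- cbind(y, -y)
  sym <- replica_averaged_pcc(cbind(x, x), y2)
  expect_lt(abs(sym$pcc), 1e-10)
  # zero-variance replica skipped with warning
  expect_warning(
    out <- replica_averaged_pcc(cbind(x, x), cbind(y, rep(1, n))),
    "skipped"
  )
  expect_equal(out$pcc, single$pcc, tolerance = 1e-12)
  expect_error(
    suppressWarnings(
      replica_averaged_pcc(cbind(x), cbind(rep(1, n)))
    ),
    "all replicas"
  )
})

test_that("dihedral angles follow the IUPAC convention", {
  # cis arrangement
  expect_equal(
    dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0
  )
  # trans arrangement
  expect_equal(
    dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180
  )
  # right-handed quarter turn
  expect_equal(
    dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90
  )
  # agreement with an independent vector-algebra oracle on random input
  set.seed(3)
  for (i in 1:25) {
    ps <- lapply(1:4, function(j) rnorm(3))
    expect_equal(
      dihedral_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]]),
      oracle_dihedral(ps[[1]], ps[[2]], ps[[3]], ps[[4]]),
      tolerance = 1e-8
    )
  }
  expect_error(
    dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "collinear"
  )
})

test_that("group distances and shell counts match brute force", {
  set.seed(8)
  coords <- matrix(rnorm(18), 6, 3)
  d <- min_pair_distance(coords, 1:3, 4:6)
  brute <- min(vapply(1:3, function(a) {
    min(vapply(4:6, function(b) {
      sqrt(sum((coords[a, ] - coords[b, ])^2))
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(d, brute)
  two <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  expect_equal(min_pair_distance(two, 1, 2), 0.5)
  expect_equal(min_pair_distance(rbind(two, two[1, ]), 1, 3), 0)
  expect_error(min_pair_distance(two, integer(0), 2), "empty")
  # shell count on a grid with known occupancy, boundary inclusive
  grid <- as.matrix(expand.grid(x = 0:2 * 0.3, y = 0, z = 0))
  expect_equal(count_within_radius(grid, 1, 2:3, radius = 0.3), 1L)
  expect_equal(count_within_radius(grid, 1, 2:3, radius = 0.6), 2L)
  expect_equal(count_within_radius(grid, 1, integer(0), radius = 0.5), 0L)
})

test_that("convergence verdict is interval intersection with the threshold band", {
  expect_true(convergence_verdict(0.0, 0.05, 0.1))
  expect_false(convergence_verdict(0.3, 0.05, 0.1))
  # interval reaches 0.09 < 0.1 -> converged
  expect_true(convergence_verdict(0.15, 0.06, 0.1))
  expect_true(convergence_verdict(-0.15, 0.06, 0.1))
  expect_error(convergence_verdict(0, 0.1, -1))
})

test_that("internal consistency verdict applies the 1 kcal/mol CI criterion", {
  v1 <- internal_consistency_verdict(
    fake_ddg(2.0, c(1.5, 2.5)), fake_ddg(-2.1, c(-2.6, -1.6))
  )
  expect_true(v1$consistent)
  expect_equal(v1$discrepancy_kcal_mol, -0.1)
  v2 <- internal_consistency_verdict(
    fake_ddg(0, c(-0.5, 0.5)), fake_ddg(0, c(-0.5, 0.5))
  )
  expect_true(v2$consistent)
  v3 <- internal_consistency_verdict(
    fake_ddg(5.0, c(4.8, 5.2)), fake_ddg(-1.0, c(-1.2, -0.8))
  )
  expect_false(v3$consistent)
  expect_equal(v3$discrepancy_kcal_mol, 4.0)
})

test_that("slow-DOF report recovers a planted coupled coordinate", {
  sys <- build_toy_system(make_planted_slow_dof(seed = 2), n_states = 6)
  cfg <- sampler_config(
    n_iterations = 250, md_steps_per_iteration = 10,
    timestep = 0.02, friction = 2, seed = 2
  )
  arc <- run_replica_exchange(sys, cfg)
  rep <- slow_dof_report(arc, n_boot = 0)
  top <- rep$per_dof$name[which.max(abs(rep$per_dof$pcc))]
  expect_equal(top, "planted_x")
  expect_gt(abs(rep$per_dof$pcc[rep$per_dof$name == "planted_x"]), 0.9)
  # the category table is ordered by descending |PCC| and led by the
  # planted coordinate's category
  expect_equal(rep$category_table$category[1], "sidechain_torsion")
  expect_true(all(diff(abs(rep$category_table$pcc)) <= 0))
  expect_false(rep$degenerate_du_dl)
  # serialization
  dir <- withr::local_tempdir()
  write_diagnostics_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "category_table.csv")))
})

test_that("a lambda-decoupled system yields a degenerate dU/dlambda report", {
  sys <- build_toy_system(
    make_planted_slow_dof(coupling = 0, bath_coupling = 0, seed = 3),
    n_states = 4
  )
  cfg <- sampler_config(
    n_iterations = 60, md_steps_per_iteration = 5,
    timestep = 0.02, seed = 3
  )
  arc <- run_replica_exchange(sys, cfg)
  rep <- slow_dof_report(arc, n_boot = 0)
  expect_true(rep$degenerate_du_dl)
  expect_true(all(is.na(rep$per_dof$pcc)))
})

test_that("multi-archive summaries order by dU/dlambda inefficiency", {
  mk_rep <- function(g) {
    structure(
      list(
        converged = TRUE, slope = 0, slope_two_se = 0.01,
        slope_threshold = 0.1,
        mixing = list(bottleneck = FALSE, subdominant_eigenvalue = 0.5),
        du_dl_g = g, degenerate_du_dl = FALSE,
        per_dof = tibble::tibble(),
        category_table = tibble::tibble(
          category = "sidechain_torsion", max_abs_pcc_dof = "x",
          pcc = 0.5, ci_lo = 0.4, ci_hi = 0.6
        ),
        delta_g_series = tibble::tibble()
      ),
      class = "diagnostics_report"
    )
  }
  tab <- combine_diagnostics(list(a = mk_rep(2), b = mk_rep(9), c = mk_rep(5)))
  expect_equal(tab$label, c("b", "c", "a"))
  expect_equal(tab$du_dl_g, c(9, 5, 2))
})
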