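atom_rec <- function(class, q_old = 0, q_new = 0, s_old = 0.3, s_new = 0.3,
                     e_old = 0.2, e_new = 0.2) {
  list(
    atom_class = class, charge_old = q_old, charge_new = q_new,
    sigma_old = s_old, sigma_new = s_new,
    epsilon_old = e_old, epsilon_new = e_new
  )
}

test_that("charge interpolation follows the per-class rules", {
  uo <- atom_rec("unique_old", q_old = 0.5)
  expect_equal(interpolate_charge(uo, 0), 0.5)
  expect_equal(interpolate_charge(uo, 1), 0)
  core <- atom_rec("core", q_old = -0.3, q_new = 0.1)
  expect_equal(interpolate_charge(core, 0.5), -0.1)
  env <- atom_rec("environment", q_old = 0.4)
  for (l in c(0, 0.3, 1)) expect_equal(interpolate_charge(env, l), 0.4)
  expect_error(interpolate_charge(env, 1.2), "lambda")
})

test_that("lifting distance follows the pair indicator rules", {
  p <- energy_params(w_lifting = 0.4)
  expect_equal(lifting_distance("unique_old", "environment", 0, p), 0)
  expect_equal(lifting_distance("unique_old", "environment", 1, p), 0.4)
  expect_equal(lifting_distance("unique_new", "core", 0, p), 0.4)
  expect_equal(lifting_distance("core", "core", 0.7, p), 0)
  expect_error(
    lifting_distance("unique_old", "unique_new", 0.5, p),
    "excluded"
  )
})

test_that("effective distance is the 4D hypotenuse", {
  expect_equal(effective_distance(0, 0.4), 0.4)
  expect_equal(effective_distance(0.3, 0.4), 0.5) # 3-4-5 triangle
  expect_equal(effective_distance(0.7, 0), 0.7)
  expect_gte(effective_distance(0.3, 0.4), 0.4)
})

test_that("direct electrostatics matches scalar hand evaluation", {
  p_plain <- energy_params(use_plain_coulomb = TRUE)
  qi <- atom_rec("core", q_old = 1, q_new = 1)
  qj <- atom_rec("core", q_old = 1, q_new = 1)
  # C q^2 / r with the Coulomb constant in reduced units
  C_hand <- 33.20637 / (0.0019872041 * 300)
  expect_equal(
    direct_electrostatics(0.3, qi, qj, 0.5, p_plain),
    C_hand / 0.3,
    tolerance = 1e-12
  )
  # zero charge
  expect_equal(
    direct_electrostatics(0.3, atom_rec("core"), qj, 0.5, p_plain), 0
  )
  # unique_old partner fully scaled out at lambda = 1
  uo <- atom_rec("unique_old", q_old = 0.8)
  expect_equal(direct_electrostatics(0.3, uo, qj, 1, p_plain), 0)
  # erfc screening reduces the plain-Coulomb value
  p_scr <- energy_params(alpha_pme = 2)
  expect_lt(
    direct_electrostatics(0.3, qi, qj, 0.5, p_scr),
    direct_electrostatics(0.3, qi, qj, 0.5, p_plain)
  )
  # alpha -> 0 reproduces Coulomb's law exactly
  p0 <- energy_params(alpha_pme = 0)
  expect_equal(
    direct_electrostatics(0.42, qi, qj, 0.3, p0),
    direct_electrostatics(0.42, qi, qj, 0.3, p_plain),
    tolerance = 1e-12
  )
  expect_error(
    direct_electrostatics(0, qi, qj, 0.5, p_plain),
    "singular"
  )
})

test_that("sterics energy has the LJ zero crossing and minimum", {
  p <- energy_params()
  a <- atom_rec("environment", s_old = 0.3, e_old = 0.25)
  b <- atom_rec("environment", s_old = 0.4, e_old = 0.36)
  sij <- 0.35
  eij <- sqrt(0.25 * 0.36)
  expect_equal(sterics_energy(sij, a, b, 0.2, p), 0, tolerance = 1e-12)
  expect_equal(
    sterics_energy(2^(1 / 6) * sij, a, b, 0.2, p),
    -eij,
    tolerance = 1e-12
  )
  # vanishing-atom pair is finite at contact thanks to the lifting
  un <- atom_rec("unique_new", e_new = 0.3, s_new = 0.3)
  env <- atom_rec("environment", e_old = 0.3)
  e_contact <- sterics_energy(0, un, env, 0, p)
  expect_true(is.finite(e_contact))
  # hand value: r_eff = w_lifting, eps_ij = 0 at lambda = 0 -> energy 0
  expect_equal(e_contact, 0)
  # at small lambda the energy turns on but stays finite
  expect_true(is.finite(sterics_energy(0, un, env, 0.1, p)))
  expect_error(
    sterics_energy(0.3, atom_rec("environment", e_old = -1), env, 0, p),
    "negative"
  )
})

test_that("endpoint identity: U(lambda=0/1) equals the physical endstate plus dummy valence", {
  p <- energy_params()
  fixtures <- list(
    fixture_chain("ALA", "THR", "apo"),
    fixture_chain("ARG", "ALA", "apo"),
    build_toy_system(make_charge_change_trio(1))
  )
  for (h in fixtures) {
    for (s in 1:2) {
      x <- random_positions(h, seed = s)
      u0 <- total_energy(x, h, 0, p)
      ref0 <- oracle_endstate_energy(h, x, "old", p) +
        oracle_dummy_valence(h, x, "new")
      expect_equal(u0, ref0, tolerance = 1e-10)
      u1 <- total_energy(x, h, 1, p)
      ref1 <- oracle_endstate_energy(h, x, "new", p) +
        oracle_dummy_valence(h, x, "old")
      expect_equal(u1, ref1, tolerance = 1e-10)
    }
  }
})

test_that("dU/dlambda matches the analytic derivative on a core pair", {
  # two core atoms, charges only, plain Coulomb:
  # U(l) = C q1(l) q2(l) / r with qi(l) = (1-l) qi_old + l qi_new
  atoms <- tibble::tibble(
    index = 1:2, name = c("A", "B"), residue_id = 1L, residue_type = "X",
    is_heavy = TRUE, charge = 0, sigma = 0.3, epsilon = 0,
    origin = "mapped",
    charge_old = c(0.5, -0.2), charge_new = c(-0.1, 0.4),
    sigma_old = 0.3, sigma_new = 0.3, epsilon_old = 0, epsilon_new = 0,
    atom_class = "core"
  )
  h <- structure(
    list(
      atoms = atoms,
      valence = tibble::tibble(
        type = character(0), i = integer(0), j = integer(0),
        k_atom = integer(0), l_atom = integer(0),
        p1 = numeric(0), p2 = numeric(0), p3 = numeric(0),
        endstate_tag = character(0)
      ),
      atom_map = structure(
        list(pairs = tibble::tibble(), mutating_residue_id = 1L),
        class = "atom_map"
      ),
      counterion = NULL,
      exclusions = matrix(integer(0), 0, 2),
      positions0 = rbind(c(0, 0, 0), c(0.4, 0, 0))
    ),
    class = "hybrid_topology"
  )
  p <- energy_params(use_plain_coulomb = TRUE)
  C <- coulomb_constant_kt(300)
  r <- 0.4
  q1 <- function(l) (1 - l) * 0.5 + l * (-0.1)
  q2 <- function(l) (1 - l) * (-0.2) + l * 0.4
  for (l in c(0.1, 0.5, 0.9)) {
    analytic <- C / r * (-0.6 * q2(l) + q1(l) * 0.6)
    expect_equal(
      du_dlambda(h$positions0, h, l, p),
      analytic,
      tolerance = 1e-6
    )
  }
})

test_that("dU/dlambda vanishes without alchemical atoms and for valence terms", {
  trio <- build_toy_system(make_charge_change_trio(1))
  inert <- trio
  inert$atoms$charge_new <- inert$atoms$charge_old
  inert$atoms$sigma_new <- inert$atoms$sigma_old
  inert$atoms$epsilon_new <- inert$atoms$epsilon_old
  p <- energy_params()
  x <- random_positions(inert, seed = 3)
  for (l in c(0, 0.25, 0.5, 1)) {
    expect_equal(du_dlambda(x, inert, l, p), 0)
  }
})

test_that("lambda protocols are evenly spaced and validated", {
  expect_equal(build_lambda_protocol(2)$lambdas, c(0, 1))
  expect_equal(
    build_lambda_protocol(5)$lambdas,
    c(0, 0.25, 0.5, 0.75, 1)
  )
  expect_equal(build_lambda_protocol(24)$n_states, 24)
  expect_equal(build_lambda_protocol(36)$n_states, 36)
  expect_error(build_lambda_protocol(1), "n_states")
  expect_error(
    build_lambda_protocol(lambdas = c(0, 0.5, 0.4, 1)),
    "increasing"
  )
})

test_that("the alchemical potential is continuous in lambda", {
  p <- energy_params()
  h <- fixture_chain("ALA", "THR", "apo")
  x <- h$positions0
  ls <- seq(0, 1, by = 1e-3)
  ce_max_slope <- max(abs(vapply(
    c(0.05, 0.25, 0.5, 0.75, 0.95),
    function(l) du_dlambda(x, h, l, p), numeric(1)
  )))
  us <- vapply(ls, function(l) total_energy(x, h, l, p), numeric(1))
  jumps <- abs(diff(us))
  expect_true(all(is.finite(us)))
  # no jump beyond what the derivative bound allows (generous factor
  # covers the softcore curvature near the endpoints)
  expect_lt(max(jumps), max(ce_max_slope, 1) * 1e-3 * 50)
})
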