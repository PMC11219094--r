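#' Energy evaluation parameters
#'
#' Bundles the electrostatics and softcore settings used by all energy
#' routines. Energies are in reduced units (kT at `temperature`),
#' distances in nm, charges in e.
#'
#' @param w_lifting Maximal 4D lifting distance (nm) of the softcore
#'   scheme; interactions involving a vanishing (dummy-bound) atom are
#'   lifted by up to this distance so they stay finite at contact.
#' @param alpha_pme Direct-space Ewald screening parameter (1/nm). Only
#'   the direct-space erfc form is implemented; reciprocal-space and
#'   self-energy terms are out of scope for non-periodic desk systems.
#' @param cutoff Nonbonded cutoff (nm); `Inf` evaluates all pairs.
#' @param use_plain_coulomb Replace the erfc screening factor by 1
#'   (plain Coulomb limit, equivalent to `alpha_pme = 0`).
#' @param dl Finite-difference step for [du_dlambda()].
#' @param temperature Reference temperature (K) fixing the reduced unit.
#' @return An `energy_params` list.
#' @export
#' @examples
#' energy_params(w_lifting = 0.4)
energy_params <- function(w_lifting = 0.4, alpha_pme = 1.0, cutoff = Inf,
                          use_plain_coulomb = FALSE, dl = 1e-4,
                          temperature = 300) {
  stopifnot(w_lifting >= 0, alpha_pme >= 0, cutoff > 0, dl > 0)
  structure(
    list(
      w_lifting = w_lifting, alpha_pme = alpha_pme, cutoff = cutoff,
      use_plain_coulomb = use_plain_coulomb, dl = dl,
      temperature = temperature,
      coulomb_constant = coulomb_constant_kt(temperature)
    ),
    class = "energy_params"
  )
}

#' Uniformly spaced alchemical protocol
#'
#' lambda_k = k / (K - 1) for k = 0, ..., K-1. A custom strictly
#' increasing schedule spanning \code{[0, 1]} can be supplied instead of
#' `n_states`.
#'
#' @param n_states Number of alchemical states K (>= 2).
#' @param lambdas Optional explicit schedule overriding the uniform one.
#' @return A `lambda_protocol` list with `lambdas` and `n_states`.
#' @export
#' @examples
#' build_lambda_protocol(5)$lambdas
build_lambda_protocol <- function(n_states, lambdas = NULL) {
  if (is.null(lambdas)) {
    if (n_states < 2) stop("n_states must be >= 2", call. = FALSE)
    lambdas <- seq(0, 1, length.out = n_states)
  }
  if (lambdas[1] != 0 || lambdas[length(lambdas)] != 1 ||
    any(diff(lambdas) <= 0)) {
    stop("lambda schedule must be strictly increasing from 0 to 1",
      call. = FALSE
    )
  }
  structure(
    list(lambdas = lambdas, n_states = length(lambdas)),
    class = "lambda_protocol"
  )
}

.check_lambda <- function(lambda) {
  if (lambda < 0 || lambda > 1) {
    stop("lambda must be in [0, 1]", call. = FALSE)
  }
}

#' Linearly interpolated per-atom charge
#'
#' unique_old atoms fade out as (1 - lambda) q_old, unique_new fade in as
#' lambda q_new, core atoms interpolate between the two endstate charges,
#' and environment atoms keep q_old.
#'
#' @param atom A list or one-row data frame with `atom_class`,
#'   `charge_old`, `charge_new`.
#' @param lambda Alchemical parameter in \code{[0, 1]}.
#' @return Charge in e.
#' @export
interpolate_charge <- function(atom, lambda) {
  .check_lambda(lambda)
  switch(atom$atom_class,
    unique_old = (1 - lambda) * atom$charge_old,
    unique_new = lambda * atom$charge_new,
    core = (1 - lambda) * atom$charge_old + lambda * atom$charge_new,
    environment = atom$charge_old,
    stop("unknown atom class", call. = FALSE)
  )
}

# per-atom lambda-interpolated LJ parameters (sigma fixed for unique atoms)
interpolate_sigma <- function(atom, lambda) {
  switch(atom$atom_class,
    unique_old = atom$sigma_old,
    unique_new = atom$sigma_new,
    core = (1 - lambda) * atom$sigma_old + lambda * atom$sigma_new,
    environment = atom$sigma_old
  )
}

interpolate_epsilon <- function(atom, lambda) {
  switch(atom$atom_class,
    unique_old = (1 - lambda) * atom$epsilon_old,
    unique_new = lambda * atom$epsilon_new,
    core = (1 - lambda) * atom$epsilon_old + lambda * atom$epsilon_new,
    environment = atom$epsilon_old
  )
}

#' Softcore lifting distance for a pair
#'
#' w = w_lifting * lambda when either atom is unique_old, w = w_lifting *
#' (1 - lambda) when either atom is unique_new, and 0 otherwise. Pairs
#' mixing a unique_old and a unique_new atom must be excluded upstream.
#'
#' @param class_i,class_j Atom classes.
#' @param lambda Alchemical parameter.
#' @param softcore An [energy_params()] (only `w_lifting` is used).
#' @return Lifting distance in nm.
#' @export
lifting_distance <- function(class_i, class_j, lambda, softcore) {
  .check_lambda(lambda)
  old_pair <- class_i == "unique_old" || class_j == "unique_old"
  new_pair <- class_i == "unique_new" || class_j == "unique_new"
  if (old_pair && new_pair) {
    stop("unique_old-unique_new pair must be excluded", call. = FALSE)
  }
  softcore$w_lifting * (old_pair * lambda + new_pair * (1 - lambda))
}

#' Effective (lifted) interaction distance
#'
#' r_eff = sqrt(r^2 + w^2): the separation in 3D space plus a 4th,
#' alchemical dimension. Equals r when w = 0 and stays positive at
#' contact whenever w > 0.
#'
#' @param r Inter-atomic distance (nm), >= 0.
#' @param w Lifting distance (nm).
#' @return Effective distance (nm).
#' @export
#' @examples
#' effective_distance(0.3, 0.4) # 3-4-5 triangle
effective_distance <- function(r, w) {
  stopifnot(all(r >= 0))
  sqrt(r^2 + w^2)
}

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Direct-space electrostatics for one pair
#'
#' U = C q_i(lambda) q_j(lambda) erfc(alpha r_eff) / r_eff, the
#' direct-space Ewald form with linearly interpolated charges and the
#' softcore-lifted distance. With `use_plain_coulomb` the erfc factor is
#' 1.
#'
#' @param r Inter-atomic distance (nm).
#' @param atom_i,atom_j Atom records (lists with `atom_class`,
#'   `charge_old`, `charge_new`).
#' @param lambda Alchemical parameter.
#' @param params An [energy_params()].
#' @return Energy in kT.
#' @export
direct_electrostatics <- function(r, atom_i, atom_j, lambda, params) {
  w <- lifting_distance(atom_i$atom_class, atom_j$atom_class, lambda, params)
  reff <- effective_distance(r, w)
  if (reff == 0) {
    stop("singular geometry: r = 0 with no softcore lifting", call. = FALSE)
  }
  qi <- interpolate_charge(atom_i, lambda)
  qj <- interpolate_charge(atom_j, lambda)
  scr <- if (params$use_plain_coulomb) 1 else erfc(params$alpha_pme * reff)
  params$coulomb_constant * qi * qj * scr / reff
}

#' Softcore Lennard-Jones sterics for one pair
#'
#' U = 4 eps_ij(lambda) x (x - 1), x = (sigma_ij(lambda) / r_eff)^6, with
#' sigma_ij the arithmetic mean of the per-atom (lambda-interpolated)
#' sigmas and eps_ij the geometric mean of the per-atom lambda-scaled
#' epsilons.
#'
#' @inheritParams direct_electrostatics
#' @return Energy in kT.
#' @export
sterics_energy <- function(r, atom_i, atom_j, lambda, params) {
  w <- lifting_distance(atom_i$atom_class, atom_j$atom_class, lambda, params)
  reff <- effective_distance(r, w)
  ei <- interpolate_epsilon(atom_i, lambda)
  ej <- interpolate_epsilon(atom_j, lambda)
  if (ei < 0 || ej < 0) stop("negative epsilon", call. = FALSE)
  eij <- sqrt(ei * ej)
  if (eij == 0) return(0)
  sij <- (interpolate_sigma(atom_i, lambda) +
    interpolate_sigma(atom_j, lambda)) / 2
  x <- (sij / reff)^6
  4 * eij * x * (x - 1)
}

# ---- compiled pairwise engine ------------------------------------------

# Precompute everything static about a hybrid topology so that energies
# and forces are vectorized over included pairs. lambda-dependence of the
# per-atom charge and epsilon is linear (q = q0 + lambda qs), which the
# engine exploits.
compile_hybrid_energy <- function(hybrid, params,
                                  rest_region = NULL, rest_config = NULL) {
  at <- hybrid$atoms
  n <- nrow(at)
  cls <- at$atom_class
  is_uo <- cls == "unique_old"
  is_un <- cls == "unique_new"
  is_core <- cls == "core"

  q0 <- ifelse(is_un, 0, at$charge_old)
  qs <- ifelse(is_uo, -at$charge_old,
    ifelse(is_un, at$charge_new,
      ifelse(is_core, at$charge_new - at$charge_old, 0)
    )
  )
  e0 <- ifelse(is_un, 0, at$epsilon_old)
  es <- ifelse(is_uo, -at$epsilon_old,
    ifelse(is_un, at$epsilon_new,
      ifelse(is_core, at$epsilon_new - at$epsilon_old, 0)
    )
  )
  s0 <- ifelse(is_un, at$sigma_new, at$sigma_old)
  ss <- ifelse(is_core, at$sigma_new - at$sigma_old, 0)

  # included pair list (i < j)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pi_ <- idx[, 1]
  pj_ <- idx[, 2]
  if (nrow(hybrid$exclusions) > 0) {
    key <- paste(hybrid$exclusions[, 1], hybrid$exclusions[, 2])
    keep <- !(paste(pi_, pj_) %in% key)
    pi_ <- pi_[keep]
    pj_ <- pj_[keep]
  }
  chi_old <- is_uo[pi_] | is_uo[pj_]
  chi_new <- is_un[pi_] | is_un[pj_]
  if (any(chi_old & chi_new)) {
    stop("internal error: unique_old-unique_new pair not excluded")
  }

  val <- hybrid$valence
  bonds_df <- val[val$type == "bond", ]
  other_df <- val[val$type != "bond", ]
  # plain-vector bond table: the hot path avoids data-frame access
  bonds <- list(
    i = as.integer(bonds_df$i), j = as.integer(bonds_df$j),
    k = as.numeric(bonds_df$p1), r0 = as.numeric(bonds_df$p2),
    n = nrow(bonds_df)
  )
  other <- if (nrow(other_df)) {
    lapply(seq_len(nrow(other_df)), function(t) as.list(other_df[t, ]))
  } else {
    list()
  }
  sites_df <- hybrid$site_restraints # optional tibble(atom, x0, y0, z0, k)
  sites <- if (!is.null(sites_df) && nrow(sites_df)) {
    list(
      atom = as.integer(sites_df$atom),
      ref = cbind(sites_df$x0, sites_df$y0, sites_df$z0),
      k = as.numeric(sites_df$k), n = nrow(sites_df)
    )
  } else {
    NULL
  }

  rest <- NULL
  if (!is.null(rest_region)) {
    p_exp <- rest_config$inter_exponent
    in_r <- function(ix) ix %in% rest_region
    # REST exponent per term: alpha^1 (rest), alpha^p (inter), alpha^0
    to_exp <- function(n_in, n_tot) {
      ifelse(n_in == n_tot, 1, ifelse(n_in == 0, 0, p_exp))
    }
    rest <- list(
      pair_e = to_exp(in_r(pi_) + in_r(pj_), 2),
      bond_e = to_exp(in_r(bonds$i) + in_r(bonds$j), 2),
      other_e = vapply(other, function(term) {
        ix <- stats::na.omit(c(term$i, term$j, term$k_atom, term$l_atom))
        to_exp(sum(in_r(ix)), length(ix))
      }, numeric(1)),
      site_e = if (!is.null(sites)) to_exp(in_r(sites$atom) + 0L, 1),
      config = rest_config
    )
  }

  # static incidence matrices turn per-pair force scatter into matmuls
  inc <- function(ia, ib) {
    m <- matrix(0, n, length(ia))
    if (length(ia)) {
      m[cbind(ia, seq_along(ia))] <- 1
      m[cbind(ib, seq_along(ib))] <- m[cbind(ib, seq_along(ib))] - 1
    }
    m
  }
  pair_inc <- inc(pi_, pj_)
  bond_inc <- inc(bonds$i, bonds$j)
  site_inc <- if (!is.null(sites)) {
    m <- matrix(0, n, sites$n)
    m[cbind(sites$atom, seq_len(sites$n))] <- 1
    m
  } else {
    NULL
  }

  list(
    n = n, q0 = q0, qs = qs, e0 = e0, es = es, s0 = s0, ss = ss,
    pi = pi_, pj = pj_, chi_old = chi_old, chi_new = chi_new,
    bonds = bonds, other = other, sites = sites, params = params,
    rest = rest, pair_inc = pair_inc, bond_inc = bond_inc,
    site_inc = site_inc
  )
}

classify_membership <- function(n_in, n_tot) {
  ifelse(n_in == n_tot, "rest", ifelse(n_in == 0, "nonrest", "inter"))
}

# vectorized pair + valence energy; returns total (and components)
eval_compiled_energy <- function(ce, positions, lambda, components = FALSE) {
  .check_lambda(lambda)
  if (any(!is.finite(positions))) stop("non-finite positions", call. = FALSE)
  p <- ce$params
  dx <- positions[ce$pi, , drop = FALSE] - positions[ce$pj, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  w <- p$w_lifting * (ce$chi_old * lambda + ce$chi_new * (1 - lambda))
  reff <- sqrt(r^2 + w^2)
  if (any(reff == 0)) {
    stop("singular geometry: r = 0 with no softcore lifting", call. = FALSE)
  }
  ql <- ce$q0 + lambda * ce$qs
  el <- ce$e0 + lambda * ce$es
  sl <- ce$s0 + lambda * ce$ss
  scr <- if (p$use_plain_coulomb) 1 else erfc(p$alpha_pme * reff)
  e_elec <- p$coulomb_constant * ql[ce$pi] * ql[ce$pj] * scr / reff
  eij <- sqrt(el[ce$pi] * el[ce$pj])
  sij <- (sl[ce$pi] + sl[ce$pj]) / 2
  x <- (sij / reff)^6
  e_lj <- 4 * eij * x * (x - 1)
  e_pair <- e_elec + e_lj
  if (is.finite(p$cutoff)) e_pair[r > p$cutoff] <- 0

  b <- ce$bonds
  e_bond <- numeric(0)
  if (b$n > 0) {
    db <- positions[b$i, , drop = FALSE] - positions[b$j, , drop = FALSE]
    rb <- sqrt(rowSums(db^2))
    e_bond <- 0.5 * b$k * (rb - b$r0)^2
  }
  e_other <- vapply(ce$other, valence_term_energy, numeric(1),
    positions = positions
  )

  e_site <- numeric(0)
  if (!is.null(ce$sites)) {
    s <- ce$sites
    ds <- positions[s$atom, , drop = FALSE] - s$ref
    e_site <- 0.5 * s$k * rowSums(ds^2)
  }
  if (!is.null(ce$rest)) {
    a <- rest_scale_factor(lambda, ce$rest$config)
    e_pair <- e_pair * a^ce$rest$pair_e
    if (length(e_bond)) e_bond <- e_bond * a^ce$rest$bond_e
    if (length(e_other)) e_other <- e_other * a^ce$rest$other_e
    if (length(e_site)) e_site <- e_site * a^ce$rest$site_e
  }
  total <- sum(e_pair) + sum(e_bond) + sum(e_other) + sum(e_site)
  if (!components) {
    return(total)
  }
  list(
    total = total, pair = e_pair, bond = e_bond, other = e_other,
    r = r, reff = reff
  )
}

valence_term_energy <- function(term, positions) {
  if (term$type == "angle") {
    a <- positions[term$i, ] - positions[term$j, ]
    b <- positions[term$k_atom, ] - positions[term$j, ]
    ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    th <- acos(pmin(1, pmax(-1, ct)))
    0.5 * term$p1 * (th - term$p2)^2
  } else if (term$type == "torsion") {
    phi <- dihedral_angle(
      positions[term$i, ], positions[term$j, ],
      positions[term$k_atom, ], positions[term$l_atom, ]
    ) * pi / 180
    term$p1 * (1 + cos(term$p3 * phi - term$p2))
  } else {
    stop("unknown valence term type: ", term$type, call. = FALSE)
  }
}

# analytic forces for pairs and bonds; numeric (per-term, local) for
# angles/torsions. Returns n x 3 matrix of forces (-dU/dx).
eval_compiled_forces <- function(ce, positions, lambda) {
  p <- ce$params
  n <- ce$n
  f <- matrix(0, n, ncol(positions))
  dx <- positions[ce$pi, , drop = FALSE] - positions[ce$pj, , drop = FALSE]
  r2 <- rowSums(dx^2)
  r <- sqrt(r2)
  w <- p$w_lifting * (ce$chi_old * lambda + ce$chi_new * (1 - lambda))
  reff <- sqrt(r2 + w^2)
  ql <- ce$q0 + lambda * ce$qs
  el <- ce$e0 + lambda * ce$es
  sl <- ce$s0 + lambda * ce$ss
  qq <- p$coulomb_constant * ql[ce$pi] * ql[ce$pj]
  # dU/dreff
  if (p$use_plain_coulomb) {
    dU_elec <- -qq / reff^2
  } else {
    a <- p$alpha_pme
    dU_elec <- -qq * erfc(a * reff) / reff^2 -
      qq * (2 * a / sqrt(pi)) * exp(-(a * reff)^2) / reff
  }
  eij <- sqrt(el[ce$pi] * el[ce$pj])
  sij <- (sl[ce$pi] + sl[ce$pj]) / 2
  sr6 <- (sij / reff)^6
  dU_lj <- 4 * eij * (-12 * sr6^2 + 6 * sr6) / reff
  dU <- dU_elec + dU_lj
  if (is.finite(p$cutoff)) dU[r > p$cutoff] <- 0
  alpha_rest <- if (is.null(ce$rest)) {
    NULL
  } else {
    rest_scale_factor(lambda, ce$rest$config)
  }
  if (!is.null(alpha_rest)) {
    dU <- dU * alpha_rest^ce$rest$pair_e
  }
  # dU/dx_i = dU/dreff * (r/reff) * (dx/r) = dU/dreff * dx / reff
  if (length(ce$pi)) {
    g <- dU / reff
    g[r == 0] <- 0 # lifted contact: radial direction undefined -> 0
    f <- f - ce$pair_inc %*% (dx * g)
  }

  b <- ce$bonds
  if (b$n > 0) {
    db <- positions[b$i, , drop = FALSE] - positions[b$j, , drop = FALSE]
    rb <- pmax(sqrt(rowSums(db^2)), 1e-12)
    gb <- b$k * (rb - b$r0) / rb
    if (!is.null(alpha_rest)) {
      gb <- gb * alpha_rest^ce$rest$bond_e
    }
    f <- f - ce$bond_inc %*% (db * gb)
  }

  if (!is.null(ce$sites)) {
    s <- ce$sites
    ds <- positions[s$atom, , drop = FALSE] - s$ref
    ks <- s$k
    if (!is.null(alpha_rest)) {
      ks <- ks * alpha_rest^ce$rest$site_e
    }
    f <- f - ce$site_inc %*% (ds * ks)
  }

  if (length(ce$other)) {
    h <- 1e-6
    for (t in seq_along(ce$other)) {
      term <- ce$other[[t]]
      ix <- stats::na.omit(c(term$i, term$j, term$k_atom, term$l_atom))
      mult <- if (is.null(alpha_rest)) 1 else alpha_rest^ce$rest$other_e[t]
      for (a in ix) {
        for (d in 1:3) {
          pp <- positions
          pp[a, d] <- pp[a, d] + h
          up <- valence_term_energy(term, pp)
          pp[a, d] <- pp[a, d] - 2 * h
          um <- valence_term_energy(term, pp)
          f[a, d] <- f[a, d] - mult * (up - um) / (2 * h)
        }
      }
    }
  }
  f
}

#' Total alchemical potential energy
#'
#' Sum of valence terms (dummy-atom valence terms are always on, so the
#' lambda = 0 potential equals the WT physical energy plus the
#' unique_new valence energy, and symmetrically at lambda = 1) plus
#' pairwise direct-space electrostatics and softcore sterics over all
#' included (non-excluded) pairs. Energy in kT.
#'
#' @param positions n x 3 coordinate matrix (nm) covering all hybrid
#'   atoms.
#' @param hybrid A `hybrid_topology`.
#' @param lambda Alchemical parameter.
#' @param params An [energy_params()].
#' @return Energy (kT).
#' @export
total_energy <- function(positions, hybrid, lambda,
                         params = energy_params()) {
  ce <- compile_hybrid_energy(hybrid, params)
  eval_compiled_energy(ce, positions, lambda)
}

#' Finite-difference dU/dlambda
#'
#' Central difference (U(lambda + dl) - U(lambda - dl)) / (2 dl), with a
#' one-sided difference at the endpoints when lambda +/- dl would leave
#' \code{[0, 1]}.
#'
#' @inheritParams total_energy
#' @param dl Step size; defaults to the value in `params`.
#' @return Energy per unit lambda (kT).
#' @export
du_dlambda <- function(positions, hybrid, lambda,
                       params = energy_params(), dl = params$dl) {
  stopifnot(dl > 0)
  ce <- compile_hybrid_energy(hybrid, params)
  du_dlambda_compiled(ce, positions, lambda, dl)
}

du_dlambda_compiled <- function(ce, positions, lambda, dl) {
  lo <- max(0, lambda - dl)
  hi <- min(1, lambda + dl)
  (eval_compiled_energy(ce, positions, hi) -
    eval_compiled_energy(ce, positions, lo)) / (hi - lo)
}
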