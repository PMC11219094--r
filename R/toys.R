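#' Toy system specifications
#'
#' Every toy system is described by a small declarative spec (kind,
#' parameters, seed) that round-trips losslessly through JSON;
#' [build_toy_system()] turns a spec into runnable objects. Analytic
#' references (exact free energies, stationary moments) are always
#' recomputed from the parameters at build time, never stored.
#'
#' @param kind One of `"harmonic_ladder"`, `"softcore_dimer"`,
#'   `"charge_change_trio"`, `"planted_slow_dof"`,
#'   `"bead_residue_chain"`.
#' @param parameters Named list of kind-specific parameters.
#' @param seed Integer seed; a fixed seed yields an identical system.
#' @return A `toy_system_spec`.
#' @export
toy_system_spec <- function(kind, parameters = list(), seed = 1L) {
  kinds <- c(
    "harmonic_ladder", "softcore_dimer", "charge_change_trio",
    "planted_slow_dof", "bead_residue_chain"
  )
  if (!kind %in% kinds) stop("unknown toy kind: ", kind, call. = FALSE)
  structure(
    list(kind = kind, parameters = parameters, seed = as.integer(seed)),
    class = "toy_system_spec"
  )
}

#' @rdname toy_system_spec
#' @param spec A `toy_system_spec`.
#' @param path File path for JSON (de)serialization.
#' @export
write_toy_spec <- function(spec, path) {
  jsonlite::write_json(
    list(
      schema = "alchemforge-toy-1", kind = spec$kind,
      parameters = spec$parameters, seed = spec$seed
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname toy_system_spec
#' @export
read_toy_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "alchemforge-toy-1")) {
    stop("unrecognized toy spec schema", call. = FALSE)
  }
  toy_system_spec(obj$kind, as.list(obj$parameters), obj$seed)
}

#' Analytic harmonic free-energy ladder
#'
#' K one-dimensional harmonic states, state k with potential
#' (K_k / 2)(x - x0_k)^2 at inverse temperature beta. The exact reduced
#' free energies f_k = (1/2) log(beta K_k / 2 pi) are available in closed
#' form (Gaussian partition functions), which makes the ladder the
#' analytic oracle for the MBAR estimator.
#'
#' @param K_states Number of states (>= 2).
#' @param spring_constants Numeric vector (recycled to `K_states`), > 0.
#' @param centers State centers (recycled).
#' @param beta Inverse temperature (reduced).
#' @param seed Seed recorded in the spec.
#' @return A `toy_system_spec`.
#' @export
#' @examples
#' s <- make_harmonic_ladder(2, spring_constants = c(1, 4))
#' build_toy_system(s)$exact_delta_f # 0.5 * log(4)
make_harmonic_ladder <- function(K_states, spring_constants = 1,
                                 centers = 0, beta = 1, seed = 1L) {
  if (K_states < 2) stop("K_states must be >= 2", call. = FALSE)
  springs <- rep_len(spring_constants, K_states)
  if (any(springs <= 0)) stop("non-positive spring constant", call. = FALSE)
  toy_system_spec("harmonic_ladder",
    parameters = list(
      K_states = K_states, spring_constants = springs,
      centers = rep_len(centers, K_states), beta = beta
    ),
    seed = seed
  )
}

#' Planted slow-degree-of-freedom landscape
#'
#' A double-well coordinate x (barrier `barrier_height` kT between minima
#' at +/- 1) is linearly coupled to lambda, so dU/dlambda contains
#' `coupling * x` by construction and x is the planted slow degree of
#' freedom. A fast harmonic bath coordinate carries a second, weaker
#' lambda coupling so that the correlation between dU/dlambda and x is
#' strong but not exactly 1; `n_spectators` additional fast harmonic
#' coordinates are uncoupled and serve as null degrees of freedom.
#'
#' @param barrier_height Barrier of the double well (kT), > 0.
#' @param coupling Linear lambda-coupling strength on x (kT per unit x).
#' @param n_spectators Number of uncoupled spectator coordinates.
#' @param bath_coupling lambda-coupling on the hidden fast bath
#'   coordinate (kT per unit).
#' @param seed Seed.
#' @return A `toy_system_spec`.
#' @export
make_planted_slow_dof <- function(barrier_height = 6, coupling = 2,
                                  n_spectators = 3, bath_coupling = 0.5,
                                  seed = 1L) {
  if (barrier_height <= 0) stop("barrier_height must be > 0", call. = FALSE)
  toy_system_spec("planted_slow_dof",
    parameters = list(
      barrier_height = barrier_height, coupling = coupling,
      n_spectators = n_spectators, bath_coupling = bath_coupling,
      k_bath = 25, k_spectator = 4
    ),
    seed = seed
  )
}

#' Charge-changing trio with a transformable water bead
#'
#' Three tethered charged beads (the middle one is the "mutating
#' residue", charge +1 at the WT endstate and 0 at the mutant endstate)
#' plus one water-like bead that the counterion transform turns into a +1
#' ion at the mutant endstate, keeping both endstates neutral. Forward
#' and reverse transformations are generated as a pair.
#'
#' @param seed Seed.
#' @return A `toy_system_spec`.
#' @export
make_charge_change_trio <- function(seed = 1L) {
  toy_system_spec("charge_change_trio",
    parameters = list(
      bead_charges = c(1, -0.1, -0.1), tether_k = 100, spacing = 1.2
    ),
    seed = seed
  )
}

#' Bead-residue chain with a single mutation and two phases
#'
#' A chain of bead residues built from the shipped templates, mutated at
#' an interior site, with a tethered water bead (counterion reservoir)
#' and, in the `complex` phase, a tethered charged partner cluster near
#' the mutation site, so that full relative free energy (ddG) workflows
#' run end to end at desk scale.
#'
#' @param n_residues Number of residues (>= 3).
#' @param mutation_site Interior residue id.
#' @param wt_type,mut_type Residue types (see [residue_types()]).
#' @param seed Seed.
#' @return A `toy_system_spec`.
#' @export
make_bead_residue_chain <- function(n_residues = 3, mutation_site = 2,
                                    wt_type = "ALA", mut_type = "THR",
                                    seed = 1L) {
  if (n_residues < 3) stop("need at least 3 residues", call. = FALSE)
  if (mutation_site <= 1 || mutation_site >= n_residues) {
    stop("mutation must be interior", call. = FALSE)
  }
  wt_type <- toupper(wt_type)
  mut_type <- toupper(mut_type)
  if (!all(c(wt_type, mut_type) %in% residue_types())) {
    stop("unknown residue type", call. = FALSE)
  }
  toy_system_spec("bead_residue_chain",
    parameters = list(
      n_residues = n_residues, mutation_site = mutation_site,
      wt_type = wt_type, mut_type = mut_type
    ),
    seed = seed
  )
}

#' Build the runnable object for a toy spec
#'
#' @param spec A `toy_system_spec`.
#' @param ... Passed to the kind-specific builder (e.g. `phase` for the
#'   bead chain).
#' @return A kind-specific system object (see the individual `make_*`
#'   documentation).
#' @export
build_toy_system <- function(spec, ...) {
  switch(spec$kind,
    harmonic_ladder = build_harmonic_ladder(spec),
    planted_slow_dof = build_planted_slow_dof(spec, ...),
    charge_change_trio = build_charge_change_trio(spec, ...),
    bead_residue_chain = build_bead_chain(spec, ...),
    stop("no builder for kind: ", spec$kind, call. = FALSE)
  )
}

build_harmonic_ladder <- function(spec) {
  p <- spec$parameters
  springs <- p$spring_constants
  centers <- p$centers
  beta <- p$beta
  K <- p$K_states
  f_exact <- 0.5 * log(beta * springs / (2 * pi))
  f_exact <- f_exact - f_exact[1]
  structure(
    list(
      kind = "harmonic_ladder", K = K,
      springs = springs, centers = centers, beta = beta,
      exact_f = f_exact, exact_delta_f = f_exact[K],
      # reduced potential of configuration x at state k
      u = function(x, k) beta * 0.5 * springs[k] * (x[1, 1] - centers[k])^2,
      force = function(x, k) {
        matrix(-beta * springs[k] * (x[1, 1] - centers[k]), 1, 1)
      },
      dudl = function(x, k) 0,
      sample_exact = function(k, n) {
        stats::rnorm(n, centers[k], sd = 1 / sqrt(beta * springs[k]))
      },
      x0 = matrix(centers[1], 1, 1),
      spec = spec
    ),
    class = c("harmonic_ladder_system", "replica_system")
  )
}

build_planted_slow_dof <- function(spec, n_states = 6, rest = NULL) {
  p <- spec$parameters
  K <- n_states
  lambdas <- build_lambda_protocol(K)$lambdas
  ns <- p$n_spectators
  # coordinate rows: 1 = x (slow), 2 = bath, 3..(2+ns) = spectators
  alpha_k <- if (is.null(rest)) {
    rep(1, K)
  } else {
    vapply(lambdas, rest_scale_factor, numeric(1), config = rest)
  }
  u <- function(x, k) {
    l <- lambdas[k]
    xx <- x[1, 1]
    b <- x[2, 1]
    y <- if (ns > 0) x[2 + seq_len(ns), 1] else numeric(0)
    alpha_k[k] * (p$barrier_height * (xx^2 - 1)^2 + l * p$coupling * xx) +
      0.5 * p$k_bath * b^2 + l * p$bath_coupling * b +
      sum(0.5 * p$k_spectator * y^2)
  }
  force <- function(x, k) {
    l <- lambdas[k]
    f <- matrix(0, nrow(x), 1)
    f[1, 1] <- -alpha_k[k] *
      (4 * p$barrier_height * x[1, 1] * (x[1, 1]^2 - 1) + l * p$coupling)
    f[2, 1] <- -(p$k_bath * x[2, 1] + l * p$bath_coupling)
    if (ns > 0) {
      f[2 + seq_len(ns), 1] <- -p$k_spectator * x[2 + seq_len(ns), 1]
    }
    f
  }
  dudl <- function(x, k) {
    # exact for AREX (u linear in lambda); finite difference handles the
    # REST-scaled case
    if (is.null(rest)) {
      p$coupling * x[1, 1] + p$bath_coupling * x[2, 1]
    } else {
      dl <- 1e-4
      l <- lambdas[k]
      lo <- max(0, l - dl)
      hi <- min(1, l + dl)
      ul <- function(lv) {
        a <- rest_scale_factor(lv, rest)
        a * (p$barrier_height * (x[1, 1]^2 - 1)^2 + lv * p$coupling * x[1, 1]) +
          0.5 * p$k_bath * x[2, 1]^2 + lv * p$bath_coupling * x[2, 1] +
          sum(0.5 * p$k_spectator * x[-(1:2), 1]^2)
      }
      (ul(hi) - ul(lo)) / (hi - lo)
    }
  }
  dofs <- c(
    list(planted_x = list(
      fn = function(x) x[1, 1], category = "sidechain_torsion"
    )),
    if (ns > 0) {
      cats <- rep(
        c("backbone_torsion", "intra_contact", "neighboring_waters"),
        length.out = ns
      )
      stats::setNames(
        lapply(seq_len(ns), function(i) {
          force_i <- i # freeze
          list(
            fn = function(x) x[2 + force_i, 1],
            category = cats[i]
          )
        }),
        paste0("spectator_", seq_len(ns))
      )
    }
  )
  structure(
    list(
      kind = "planted_slow_dof", K = K, lambdas = lambdas,
      u = u, force = force, dudl = dudl, dofs = dofs,
      x0 = matrix(c(-1, rep(0, 1 + ns)), ncol = 1),
      rest = rest, spec = spec
    ),
    class = c("planted_slow_dof_system", "replica_system")
  )
}

build_charge_change_trio <- function(spec, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  p <- spec$parameters
  qs <- p$bead_charges
  pos <- rbind(
    c(0, 0, 0),
    c(p$spacing, 0, 0),
    c(-p$spacing, 0, 0),
    c(0, p$spacing, 0)
  )
  atoms <- tibble::tibble(
    index = 1:4,
    name = c("X", "B1", "B2", "WAT"),
    residue_id = c(2L, 1L, 3L, 4L),
    residue_type = c("BEAD", "BEAD", "BEAD", "WAT"),
    is_heavy = TRUE,
    charge = c(qs, 0),
    sigma = c(0.32, 0.32, 0.32, 0.31),
    epsilon = c(0.4, 0.4, 0.4, 0.65),
    origin = "mapped",
    charge_old = c(qs, 0),
    sigma_old = c(0.32, 0.32, 0.32, 0.31),
    epsilon_old = c(0.4, 0.4, 0.4, 0.65),
    charge_new = c(0, qs[2], qs[3], 0),
    sigma_new = c(0.32, 0.32, 0.32, 0.31),
    epsilon_new = c(0.4, 0.4, 0.4, 0.65),
    atom_class = c("core", "environment", "environment", "environment")
  )
  valence <- tibble::tibble(
    type = character(0), i = integer(0), j = integer(0),
    k_atom = integer(0), l_atom = integer(0),
    p1 = numeric(0), p2 = numeric(0), p3 = numeric(0),
    endstate_tag = character(0)
  )
  amap <- structure(
    list(
      pairs = tibble::tibble(
        name = atoms$name, wt_index = 1:4, mut_index = 1:4
      ),
      mutating_residue_id = 2L
    ),
    class = "atom_map"
  )
  hybrid <- structure(
    list(
      atoms = atoms, valence = valence, atom_map = amap,
      counterion = NULL,
      exclusions = matrix(integer(0), 0, 2,
        dimnames = list(NULL, c("i", "j"))
      ),
      positions0 = pos,
      site_restraints = tibble::tibble(
        atom = 1:4, x0 = pos[, 1], y0 = pos[, 2], z0 = pos[, 3],
        k = p$tether_k
      )
    ),
    class = "hybrid_topology"
  )
  hybrid <- apply_counterion_transform(hybrid, water_like_particles = 4L)
  if (direction == "reverse") hybrid <- reverse_hybrid(hybrid)
  hybrid
}

#' Reverse a hybrid topology (swap the two endstates)
#'
#' Exchanges old/new nonbonded parameters, swaps unique_old and
#' unique_new classes and old/new valence tags, so that
#' U_rev(x; lambda) = U_fwd(x; 1 - lambda).
#'
#' @param hybrid A `hybrid_topology`.
#' @return The reversed `hybrid_topology`.
#' @export
reverse_hybrid <- function(hybrid) {
  at <- hybrid$atoms
  swap <- function(a, b) {
    tmp <- at[[a]]
    at[[a]] <<- at[[b]]
    at[[b]] <<- tmp
  }
  swap("charge_old", "charge_new")
  swap("sigma_old", "sigma_new")
  swap("epsilon_old", "epsilon_new")
  at$atom_class <- dplyr::recode(at$atom_class,
    unique_old = "unique_new", unique_new = "unique_old"
  )
  hybrid$atoms <- at
  hybrid$valence$endstate_tag <- dplyr::recode(hybrid$valence$endstate_tag,
    old = "new", new = "old"
  )
  if (!is.null(hybrid$counterion) &&
    !is.null(hybrid$counterion$water_index)) {
    hybrid$counterion$ion_charge <- -hybrid$counterion$ion_charge
  }
  hybrid
}

# deterministic chain layout: backbone on a line, side chains grown
# outward along the bond graph
make_chain_positions <- function(atoms, bonds, seed) {
  set.seed(seed)
  n <- nrow(atoms)
  pos <- matrix(NA_real_, n, 3)
  local_bb <- list(
    N = c(0, 0, 0), H = c(-0.06, 0.08, 0), CA = c(0.15, 0, 0),
    HA = c(0.15, -0.11, 0), C = c(0.30, 0.05, 0), O = c(0.30, 0.20, 0)
  )
  spacing <- 0.45
  for (rid in unique(atoms$residue_id)) {
    sel <- atoms$residue_id == rid
    nm <- atoms$name[sel]
    offs <- (rid - 1) * spacing
    for (k in which(sel)) {
      if (atoms$name[k] %in% names(local_bb)) {
        pos[k, ] <- local_bb[[atoms$name[k]]] + c(offs, 0, 0)
      }
    }
  }
  # grow remaining atoms (side chains) from placed neighbours
  todo <- which(is.na(pos[, 1]))
  guard <- 0
  while (length(todo) > 0 && guard < 100) {
    guard <- guard + 1
    for (a in todo) {
      nb <- c(bonds$j[bonds$i == a], bonds$i[bonds$j == a])
      nb <- nb[!is.na(pos[nb, 1])]
      if (length(nb) == 0) next
      parent <- nb[1]
      r0 <- bonds$r0[(bonds$i == a & bonds$j == parent) |
        (bonds$j == a & bonds$i == parent)][1]
      # bias away from the backbone line (y direction) with seeded jitter
      dir <- c(0, 1, 0) + 0.6 * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pos[a, ] <- pos[parent, ] + r0 * dir
      todo <- setdiff(todo, a)
    }
  }
  if (length(todo)) stop("disconnected atom in chain layout", call. = FALSE)
  pos
}

#' Assemble a plain (non-alchemical) bead chain system
#'
#' @param residue_types_vec Character vector of residue types, one per
#'   residue.
#' @param seed Layout seed.
#' @param water Add a tethered water-like bead (counterion reservoir).
#' @param partner Add a tethered 3-bead charged partner cluster
#'   (the `complex` phase environment).
#' @param mutation_site Residue the water/partner are placed near.
#' @return List with `atoms`, `bonds`, `positions`, `site_restraints`.
#' @export
make_chain_system <- function(residue_types_vec, seed = 1L, water = TRUE,
                              partner = FALSE,
                              mutation_site = ceiling(length(residue_types_vec) / 2)) {
  atoms_l <- list()
  bonds_l <- list()
  off <- 0L
  for (rid in seq_along(residue_types_vec)) {
    tpl <- residue_template(residue_types_vec[rid])
    atoms_l[[rid]] <- tpl |>
      dplyr::mutate(
        index = off + dplyr::row_number(),
        residue_id = rid,
        residue_type = residue_types_vec[rid]
      )
    rb <- residue_bonds(residue_types_vec[rid])
    bonds_l[[rid]] <- tibble::tibble(
      i = off + match(rb$a, tpl$name),
      j = off + match(rb$b, tpl$name),
      r0 = rb$r0, k = rb$k
    )
    off <- off + nrow(tpl)
  }
  atoms <- dplyr::bind_rows(atoms_l)
  bonds <- dplyr::bind_rows(bonds_l)
  # peptide bonds C(i) - N(i+1)
  for (rid in seq_len(length(residue_types_vec) - 1)) {
    ci <- atoms$index[atoms$residue_id == rid & atoms$name == "C"]
    nj <- atoms$index[atoms$residue_id == rid + 1 & atoms$name == "N"]
    bonds <- dplyr::bind_rows(
      bonds, tibble::tibble(i = ci, j = nj, r0 = 0.15, k = 2500)
    )
  }
  pos <- make_chain_positions(atoms, bonds, seed)

  mut_ca <- pos[atoms$index[atoms$residue_id == mutation_site &
    atoms$name == "CA"], ]
  sites <- tibble::tibble(
    atom = atoms$index[atoms$name == "CA"],
    x0 = pos[atoms$name == "CA", 1],
    y0 = pos[atoms$name == "CA", 2],
    z0 = pos[atoms$name == "CA", 3],
    k = 5
  )
  extra <- function(names, rtype, charges, sig, eps, xyz, tether) {
    n0 <- nrow(atoms)
    atoms <<- dplyr::bind_rows(atoms, tibble::tibble(
      name = names, is_heavy = TRUE, charge = charges,
      sigma = sig, epsilon = eps,
      index = n0 + seq_along(names),
      residue_id = max(atoms$residue_id) + 1L,
      residue_type = rtype
    ))
    pos <<- rbind(pos, xyz)
    sites <<- dplyr::bind_rows(sites, tibble::tibble(
      atom = n0 + seq_along(names),
      x0 = xyz[, 1], y0 = xyz[, 2], z0 = xyz[, 3], k = tether
    ))
  }
  if (water) {
    extra("WO", "WAT", 0, 0.31, 0.65,
      matrix(mut_ca + c(0, 0.8, 0.3), 1, 3),
      tether = 20
    )
  }
  if (partner) {
    extra(c("P1", "P2", "P3"), "PRT", c(0.4, -0.4, 0.3),
      rep(0.34, 3), rep(0.4, 3),
      rbind(
        mut_ca + c(-0.3, -0.75, 0),
        mut_ca + c(0.3, -0.75, 0),
        mut_ca + c(0, -0.75, 0.4)
      ),
      tether = 20
    )
  }
  list(atoms = atoms, bonds = bonds, positions = pos, site_restraints = sites)
}

build_bead_chain <- function(spec, phase = c("apo", "complex")) {
  phase <- match.arg(phase)
  p <- spec$parameters
  # alanine scaffold with the WT residue at the mutation site
  sys <- make_chain_system(
    replace(rep("ALA", p$n_residues), p$mutation_site, p$wt_type),
    seed = spec$seed,
    water = TRUE, partner = (phase == "complex"),
    mutation_site = p$mutation_site
  )
  hybrid <- build_hybrid_topology(
    sys, p$mutation_site, p$mut_type,
    seed = spec$seed
  )
  hybrid$site_restraints <- sys$site_restraints
  water_ix <- hybrid$atoms$index[hybrid$atoms$residue_type == "WAT"]
  dq <- sum(hybrid$atoms$charge_new) - sum(hybrid$atoms$charge_old)
  if (abs(dq) > 1e-12) {
    hybrid <- apply_counterion_transform(hybrid, water_ix)
  } else {
    validate_hybrid_topology(hybrid)
  }
  hybrid
}
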